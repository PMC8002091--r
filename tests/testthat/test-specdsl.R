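test_that("specification schema errors are caught at construction", {
  sg <- seed_graph(2, rbind(c(1, 2)), "ge2")
  gam <- all_edge_configs(c("C", "O"))
  # crossed length bounds
  expect_error(target_spec(sg, 2, n_star = 10, n_lb = 4,
                           interior = list(l_lb = 3, l_ub = 2),
                           chem = list(lambda_int = c("C", "O"),
                                       gamma_int = gam, fringe_e = "(C0)")),
               "l_lb exceeds l_ub")
  # fringe tree taller than rho
  expect_error(target_spec(sg, 1, n_star = 10, n_lb = 4,
                           chem = list(lambda_int = c("C", "O"),
                                       gamma_int = gam,
                                       fringe_e = "(C0(C1(C1)))")),
               "taller than rho")
  # unknown element
  expect_error(target_spec(sg, 2, n_star = 10, n_lb = 4,
                           chem = list(lambda_int = c("C", "Xx"),
                                       gamma_int = gam, fringe_e = "(C0)")),
               "unknown element")
  expect_error(seed_graph(2, rbind(c(1, 2)), "between1and2"), "classes")
})

test_that("specifications round-trip through JSON byte-identically", {
  set.seed(91)
  for (rep in 1:20) {
    n_star <- sample(10:20, 1)
    spec <- toy_spec(n_star = n_star,
                     l_ub = c(sample(2:5, 1), sample(1:4, 1)),
                     side = list(list(coef = c(a1 = 1, a2 = -1), op = ">=", rhs = 0)))
    f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
    write_target_spec(spec, f1)
    spec2 <- read_target_spec(f1)
    write_target_spec(spec2, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_equal(spec2$interior, spec$interior)
    expect_equal(spec2$chem$f_star, spec$chem$f_star)
  }
})

test_that("the Ib-style defaults (all lower bounds 0, upper bounds n*) apply", {
  sg <- seed_graph(2, rbind(c(1, 2), c(1, 2)), c("ge2", "ge1"))
  spec <- target_spec(sg, 2, n_star = 38, n_lb = 6,
                      chem = list(lambda_int = c("C", "N", "O"),
                                  gamma_int = all_edge_configs(c("C", "N", "O")),
                                  fringe_e = toy_fringe_codes()))
  expect_true(all(spec$interior$bl_lb == 0))
  expect_true(all(spec$interior$bd2_lb == 0))
  expect_true(all(spec$interior$bd2_ub == 38))
  expect_true(all(spec$chem$na_ub == 38))
  expect_equal(spec$interior$l_lb, c(2L, 1L))   # forced by the edge classes
})

test_that("subdivision testing finds correspondences and names violations", {
  sg <- seed_graph(2, rbind(c(1, 2), c(1, 2)), c("ge2", "ge1"))
  # a 4-cycle: one path of length 2, one of length 2
  s1 <- chem_graph(4, rbind(c(1, 3), c(3, 2), c(1, 4), c(4, 2)), rep("C", 4), rep(1, 4))
  r1 <- is_subdivision(s1, sg)
  expect_true(r1$ok)
  expect_length(r1$paths, 2L)
  # a triangle: the ge2 edge must take the 2-path, ge1 the direct edge
  s2 <- chem_graph(3, rbind(c(1, 2), c(1, 3), c(3, 2)), rep("C", 3), rep(1, 3))
  expect_true(is_subdivision(s2, sg)$ok)
  # single edge: the ge2 edge cannot be realized
  sg2 <- seed_graph(2, rbind(c(1, 2)), "ge2")
  s3 <- chem_graph(2, rbind(c(1, 2)), c("C", "C"), 1)
  r3 <- is_subdivision(s3, sg2)
  expect_false(r3$ok)
  expect_equal(r3$rule, "class_ge2")
  expect_equal(r3$edge, "a1")
  # degenerate: the seed graph itself (ge1 kept as an edge, e01 kept)
  sg3 <- seed_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)), c("ge1", "eq1", "e01"))
  s4 <- chem_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)), rep("C", 3), rep(1, 3))
  expect_true(is_subdivision(s4, sg3)$ok)
})

test_that("sampled extensions validate and targeted mutations are flagged", {
  trn <- toy_training()
  spec <- trn$spec
  set.seed(103)
  for (rep in 1:8) {
    g <- random_extension(spec)
    expect_false(is.null(g))
    rep_v <- validate_extension(g, spec)
    expect_true(rep_v$is_extension)
    # shrink n*: exactly the size rule is flagged
    spec_n <- spec
    spec_n$chem$n_star <- g$n - 1L
    r <- validate_extension(g, spec_n)
    expect_false(r$is_extension)
    expect_true("n" %in% vapply(r$violations, `[[`, character(1), "rule"))
    # demand an edge-configuration count above anything attainable
    spec_ec <- spec
    key <- names(spec_ec$chem$ec_int_lb)[1L]
    spec_ec$chem$ec_int_lb[[key]] <- spec$chem$n_star
    r2 <- validate_extension(g, spec_ec)
    expect_false(r2$is_extension)
    expect_true(any(grepl("^ec_int", vapply(r2$violations, `[[`, character(1), "rule"))))
  }
})

test_that("validation is invariant under relabeling", {
  trn <- toy_training()
  set.seed(107)
  for (rep in 1:5) {
    g <- random_extension(trn$spec)
    h <- cg_permute(g, sample(g$n))
    expect_true(validate_extension(h, trn$spec)$is_extension)
  }
})

test_that("an infeasible specification yields no extension", {
  # demands more double-bond interior edges than interior vertices allow
  spec <- toy_spec(n_int = c(3L, 4L), l_ub = c(3L, 2L))
  spec$chem$ec_int_lb[["C2,C2,1"]] <- 50
  expect_null(random_extension(spec, rng_seed = 1, attempts = 40))
})

test_that("exhaustive enumeration agrees with the validator and the sampler", {
  spec <- toy_spec(n_star = 12L, n_int = c(3L, 4L), l_ub = c(3L, 2L),
                   lambda = c("C", "O"),
                   fringe = c("(C0)", "(O0)", "(C0(C1(C1)))"))
  exts <- enumerate_extensions(spec)
  expect_gt(length(exts), 0L)
  certs <- vapply(exts, cg_certificate, character(1))
  expect_false(anyDuplicated(certs) > 0)
  for (g in exts[seq_len(min(25, length(exts)))]) {
    expect_true(validate_extension(g, spec)$is_extension)
  }
  set.seed(11)
  for (rep in 1:10) {
    g <- random_extension(spec)
    expect_true(cg_certificate(g) %in% certs)
  }
})
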