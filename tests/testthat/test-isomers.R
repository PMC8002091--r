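# shared fixture: 6-ring specification where fringe placement creates
# nontrivial isomer classes
ring_spec <- function(fringes = c("(C0)", "(C0(C1(C1)))", "(C0(O1(C1)))"),
                      lambda = c("C", "O"), n_star = 20L) {
  cyc <- cbind(1:6, c(2:6, 1))
  sg <- seed_graph(6, cyc, rep("eq1", 6))
  target_spec(sg, rho = 2, n_star = n_star, n_lb = 6, n_int_lb = 6, n_int_ub = 6,
              interior = list(v_bl_ub = 0),
              chem = list(lambda_int = lambda,
                          gamma_int = all_edge_configs(lambda),
                          fringe_e = fringes))
}

ring_graph <- function(positions, codes,
                       alpha = rep("C", 6), beta = rep(1L, 6)) {
  cyc <- cbind(1:6, c(2:6, 1))
  fr <- rep(list(NULL), 6)
  for (j in seq_along(positions)) fr[[positions[j]]] <- parse_fringe_code(codes[j])
  moldesign:::assemble_graph(6, cyc, alpha, beta, fr, default_element_table())
}

test_that("a fully pinned instance has exactly itself as isomer", {
  spec <- ring_spec(fringes = c("(C0)", "(C0(C1(C1)))"))
  g <- ring_graph(1:6, rep("(C0(C1(C1)))", 6))
  space <- build_descriptor_space(list(g), 2)
  en <- enumerate_isomers(g, spec, space)
  expect_length(en$graphs, 1L)
  expect_equal(en$lower_bound, 1)
  expect_true(en$exhausted)
  expect_true(cg_isomorphic(en$graphs[[1L]], g))
  expect_equal(count_lower_bound(g, spec), 1)
})

test_that("fringe placements at equal feature vectors are recovered up to isomorphism", {
  spec <- ring_spec()
  g3 <- ring_graph(c(1, 3), c("(C0(C1(C1)))", "(C0(O1(C1)))"))
  g4 <- ring_graph(c(1, 4), c("(C0(C1(C1)))", "(C0(O1(C1)))"))
  space <- build_descriptor_space(list(g3, g4), 2)
  expect_equal(feature_vector(g3, space), feature_vector(g4, space))
  expect_false(cg_isomorphic(g3, g4))
  en <- enumerate_isomers(g3, spec, space)
  expect_true(en$exhausted)
  expect_length(en$graphs, 2L)
  certs <- vapply(en$graphs, cg_certificate, character(1))
  expect_setequal(certs, c(cg_certificate(g3), cg_certificate(g4)))
  # output order is deterministic
  en2 <- enumerate_isomers(g3, spec, space)
  expect_equal(vapply(en2$graphs, cg_certificate, character(1)), certs)
  # the permutation lower bound never exceeds the exact count
  expect_lte(count_lower_bound(g3, spec), 2)
})

test_that("enumeration equals brute force over all assignments on toy instances", {
  spec <- ring_spec()
  g <- ring_graph(c(1, 3), c("(C0(C1(C1)))", "(C0(O1(C1)))"))
  space <- build_descriptor_space(list(g,
    ring_graph(c(1, 4), c("(C0(C1(C1)))", "(C0(O1(C1)))")),
    ring_graph(c(1, 2), c("(C0(C1(C1)))", "(C0(O1(C1)))"))), 2)
  target <- feature_vector(g, space)
  # independent brute force: place the two distinct fringes on every ordered
  # pair of ring positions, filter by feature equality and spec validity,
  # deduplicate by pairwise isomorphism
  found <- list()
  for (i in 1:6) for (j in setdiff(1:6, i)) {
    h <- ring_graph(c(i, j), c("(C0(C1(C1)))", "(C0(O1(C1)))"))
    fv <- feature_vector(h, space)
    if (any(abs(fv - target) > 1e-12)) next
    if (!validate_extension(h, spec)$is_extension) next
    if (!any(vapply(found, cg_isomorphic, logical(1), g1 = h))) {
      found[[length(found) + 1L]] <- h
    }
  }
  en <- enumerate_isomers(g, spec, space)
  expect_true(en$exhausted)
  expect_equal(length(en$graphs), length(found))
  expect_setequal(vapply(en$graphs, cg_certificate, character(1)),
                  vapply(found, cg_certificate, character(1)))
})

test_that("interior relabelings preserving all counts are found too", {
  # alternate C/O ring admits rotations; oxygen placement classes
  spec <- ring_spec(fringes = c("(C0)", "(O0)"), lambda = c("C", "O"))
  g <- ring_graph(integer(0), character(0),
                  alpha = c("O", "C", "C", "O", "C", "C"))
  space <- build_descriptor_space(list(g), 2)
  en <- enumerate_isomers(g, spec, space)
  expect_true(en$exhausted)
  # brute force over all 2-of-6 oxygen placements with the same feature vector
  target <- feature_vector(g, space)
  found <- list()
  combs <- utils::combn(6, 2)
  for (cix in seq_len(ncol(combs))) {
    alpha <- rep("C", 6); alpha[combs[, cix]] <- "O"
    h <- tryCatch(ring_graph(integer(0), character(0), alpha = alpha),
                  error = function(e) NULL)
    if (is.null(h)) next
    fv <- tryCatch(feature_vector(h, space), error = function(e) NULL)
    if (is.null(fv) || any(abs(fv - target) > 1e-12)) next
    if (!validate_extension(h, spec)$is_extension) next
    if (!any(vapply(found, cg_isomorphic, logical(1), g1 = h))) {
      found[[length(found) + 1L]] <- h
    }
  }
  expect_equal(length(en$graphs), length(found))
})

test_that("the cap stops enumeration with a truthful flag and bound", {
  spec <- ring_spec()
  g3 <- ring_graph(c(1, 3), c("(C0(C1(C1)))", "(C0(O1(C1)))"))
  space <- build_descriptor_space(list(g3,
    ring_graph(c(1, 4), c("(C0(C1(C1)))", "(C0(O1(C1)))"))), 2)
  en <- enumerate_isomers(g3, spec, space, limit = 1L)
  expect_length(en$graphs, 1L)
  expect_false(en$exhausted)
  expect_gte(en$lower_bound, 1)
  expect_error(enumerate_isomers(chem_graph(2, rbind(c(1, 2)), c("C", "C"), 1),
                                 spec, space), "specification")
})
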