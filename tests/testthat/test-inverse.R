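test_that("the MILP network encoding reproduces trivial forward passes", {
  # zero weights: the MILP output is the output bias
  net0 <- structure(list(weights = list(matrix(0, 2, 2), matrix(0, 2, 1)),
                         biases = list(c(0, 0), 0.75),
                         architecture = c(2L, 2L, 1L)), class = "mlp_net")
  expect_equal(encode_forward_pass(net0, c(0, 0)), 0.75, tolerance = 1e-9)
  # hand-set single hidden unit
  net1 <- structure(list(weights = list(matrix(c(1, -1), 2, 1), matrix(2, 1, 1)),
                         biases = list(0.5, -1),
                         architecture = c(2L, 1L, 1L)), class = "mlp_net")
  box <- rbind(c(-5, -5), c(5, 5))
  x <- rbind(c(3, 1), c(0, 5), c(-5, 5), c(5, -5))
  expect_equal(encode_forward_pass(net1, x, input_box = box),
               predict(net1, x), tolerance = 1e-6)
})

test_that("the encoding stays exact at the propagation box edges", {
  set.seed(131)
  K <- 5
  net <- structure(list(weights = list(matrix(rnorm(K * 4), K, 4),
                                       matrix(rnorm(4), 4, 1)),
                        biases = list(rnorm(4), rnorm(1)),
                        architecture = c(K, 4L, 1L)), class = "mlp_net")
  box <- rbind(rep(-4, K), rep(4, K))
  corners <- rbind(rep(-4, K), rep(4, K),
                   c(-4, 4, -4, 4, -4), c(4, -4, 4, -4, 4))
  expect_equal(encode_forward_pass(net, corners, input_box = box),
               predict(net, corners), tolerance = 1e-6)
})

test_that("an unsatisfiable size demand makes the instance infeasible", {
  trn <- toy_training()
  spec <- trn$spec
  spec$interior$n_int_lb <- 5L
  spec$interior$n_int_ub <- 4L
  inst <- formulate_inverse(spec, trn$rnet, trn$rspace, y_star = 0, eps = 100)
  r <- solve_inverse(inst, time_limit = 60)
  expect_equal(r$status, "infeasible")
})

test_that("inversion returns verified graphs at witness-derived targets", {
  trn <- toy_training()
  set.seed(211)
  for (rep in 1:3) {
    w <- random_extension(trn$spec)
    y_star <- predict(trn$rnet, feature_vector(w, trn$rspace))
    inst <- formulate_inverse(trn$spec, trn$rnet, trn$rspace, y_star, eps = 1e-4)
    r <- solve_inverse(inst, time_limit = 300)
    expect_equal(r$status, "feasible")
    expect_true(isTRUE(r$verified), info = paste(attr(r$verified, "diagnosis"), collapse = "; "))
    expect_lte(abs(r$predicted - y_star), 1e-4 + 1e-6)
    # the decoded feature vector equals a from-scratch featurization
    expect_equal(r$feature_vector, feature_vector(r$graph, trn$rspace))
  }
})

test_that("verification fails loudly on perturbed results", {
  trn <- toy_training()
  w <- random_extension(trn$spec, rng_seed = 303)
  y_star <- predict(trn$rnet, feature_vector(w, trn$rspace))
  inst <- formulate_inverse(trn$spec, trn$rnet, trn$rspace, y_star, eps = 1e-4)
  r <- solve_inverse(inst, time_limit = 300)
  expect_true(isTRUE(r$verified))
  # a descriptor perturbed by one must be named in the diagnosis
  r_bad <- r
  slot <- grep("^fc_", names(r_bad$feature_vector))[1L]
  r_bad$feature_vector[slot] <- r_bad$feature_vector[slot] + 1
  v <- verify_inference(r_bad, trn$rnet, trn$rspace, trn$spec)
  expect_false(isTRUE(v))
  expect_true(any(grepl("descriptor mismatch", attr(v, "diagnosis"))))
  # mutating the graph against the spec is caught
  r_mut <- r
  r_mut$graph <- chem_graph(2, rbind(c(1, 2)), c("C", "C"), 1)
  v2 <- verify_inference(r_mut, trn$rnet, trn$rspace, trn$spec)
  expect_false(isTRUE(v2))
})

test_that("feasibility scanning classifies targets on both sides of the range", {
  trn <- toy_training()
  w <- random_extension(trn$spec, rng_seed = 401)
  y_w <- predict(trn$rnet, feature_vector(w, trn$rspace))
  # a grid far outside any attainable prediction plus the witness value
  grid <- c(y_w - 1e5, y_w, y_w + 1e5)
  scan <- feasibility_scan(trn$spec, trn$rnet, trn$rspace, grid,
                           eps = 1e-3, time_limit = 120)
  expect_equal(scan$table$status[2L], "feasible")
  expect_equal(scan$table$status[c(1L, 3L)], c("infeasible", "infeasible"))
  expect_equal(scan$y_range, c(y_w, y_w))
})

test_that("instance sizes grow linearly in n* at fixed interior size", {
  trn <- toy_training()
  sizes <- vapply(c(10L, 20L, 30L), function(ns) {
    spec <- toy_spec(n_star = ns, gamma = trn$spec$chem$gamma_int,
                     fringe = trn$spec$chem$f_star)
    net <- trn$rnet
    inst <- formulate_inverse(spec, net, trn$rspace, 0, eps = 1e9)
    inst$counts[["variables"]]
  }, numeric(1))
  d1 <- diff(sizes)
  # successive increments agree within 60%: linear, not quadratic, growth
  expect_lt(abs(d1[2L] - d1[1L]) / d1[1L], 0.6)
})
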