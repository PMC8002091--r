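test_that("forward pass matches hand-computed values", {
  # all-zero weights: output equals the output bias
  net0 <- structure(list(weights = list(matrix(0, 3, 2), matrix(0, 2, 1)),
                         biases = list(c(0, 0), 1.25),
                         architecture = c(3L, 2L, 1L)), class = "mlp_net")
  expect_equal(predict(net0, c(5, -2, 7)), 1.25)
  # single hidden unit, hand-set weights: y = 2 relu(x1 - x2 + 0.5) - 1
  net1 <- structure(list(weights = list(matrix(c(1, -1), 2, 1), matrix(2, 1, 1)),
                         biases = list(0.5, -1),
                         architecture = c(2L, 1L, 1L)), class = "mlp_net")
  expect_equal(predict(net1, c(3, 1)), 2 * (3 - 1 + 0.5) - 1)
  expect_equal(predict(net1, c(0, 5)), -1)     # relu clamps at 0
  expect_error(predict(net1, c(1, 2, 3)), "expects")
})

test_that("training recovers an exactly representable property", {
  trn <- toy_training()
  expect_gte(trn$net$r2_train, 0.99)
  x <- feature_matrix(trn$dataset, trn$space)
  expect_equal(r_squared(trn$net, x, trn$dataset$values), trn$net$r2_train)
  expect_length(residuals(trn$net), length(trn$dataset))
})

test_that("a piecewise-linear response is learnable by one ReLU layer", {
  trn <- toy_training()
  x <- feature_matrix(trn$dataset, trn$space)
  y <- pmax(x[, "n"] - 8, 0) * 2 + pmax(6 - x[, "n_int"], 0) - 3
  net <- mlp_fit(x, y, hidden = 16L, seed = 5, epochs = 3000)
  expect_gte(r_squared(net, x, y), 0.9)
})

test_that("the coefficient of determination follows the printed formula", {
  x <- matrix(1:5, 5, 1)
  y <- c(2, 4, 5, 4, 6)
  # constant predictor at 3 (zero weights, output bias 3): hand-worked R^2
  const3 <- structure(list(weights = list(matrix(0, 1, 1), matrix(0, 1, 1)),
                           biases = list(0, 3), architecture = c(1L, 1L, 1L)),
                      class = "mlp_net")
  sse <- sum((y - 3)^2); sst <- sum((y - mean(y))^2)
  expect_equal(r_squared(const3, x, y), 1 - sse / sst)
  # a constant predictor at the mean scores exactly 0
  constm <- const3; constm$biases[[2L]] <- mean(y)
  expect_equal(r_squared(constm, x, y), 0)
  # a perfect predictor scores exactly 1
  perfect <- structure(list(weights = list(matrix(1, 1, 1), matrix(1, 1, 1)),
                            biases = list(0, 0), architecture = c(1L, 1L, 1L)),
                       class = "mlp_net")
  expect_equal(r_squared(perfect, matrix(y, 5, 1), y), 1)
  expect_error(r_squared(perfect, matrix(1, 2, 1), c(3, 3)), "constant")
  expect_error(r_squared(perfect, matrix(1, 1, 1), 3), "fewer than two")
})

test_that("cross-validation folds are seed-stable and aggregate correctly", {
  cfg <- synthetic_config(noise_sd = 0, n_graphs = 150L)
  ds <- generate_synthetic_dataset(cfg, seed = 19)
  sp <- build_descriptor_space(ds, 2)
  x <- feature_matrix(ds, sp)
  y <- ds$values
  cv <- mlp_cross_validate(x, y, architectures = list(8L),
                           fold_seed = 2, train_seed = 1, epochs = 3000)
  expect_equal(cv$t_rcv2, rowMeans(cv$r2))
  expect_equal(cv$t_rmax2, max(cv$r2))
  # same fold seed, different run: fold membership pattern is unchanged
  cv2 <- mlp_cross_validate(x, y, architectures = list(4L),
                            fold_seed = 2, train_seed = 1, epochs = 10)
  expect_equal(cv2$fold, cv$fold)
  # an exactly linear property generalizes across folds
  expect_true(all(cv$r2[1L, ] >= 0.95))
})

test_that("input reduction drops exactly the inactive slots and preserves outputs", {
  trn <- toy_training()
  # keeping everything is the identity
  spec_full <- trn$spec
  spec_full$chem$gamma_int <- trn$space$gamma_int
  spec_full$chem$f_star <- trn$space$fringe_set
  red_full <- reduce_inputs(trn$net, trn$space, spec_full)
  expect_equal(red_full$space$K, trn$space$K)
  expect_equal(red_full$net$weights[[1L]], trn$net$weights[[1L]])
  # the toy spec keeps a subset; dropped slots are provably zero on
  # conforming graphs, so predictions agree exactly
  red <- reduce_inputs(trn$net, trn$space, trn$spec)
  expect_equal(trn$space$K - red$space$K,
               length(trn$space$fringe_set) - length(trn$spec$chem$f_star) +
                 length(trn$space$gamma_int) - length(trn$spec$chem$gamma_int))
  set.seed(13)
  for (rep in 1:10) {
    g <- random_extension(trn$spec)
    full <- predict(trn$net, feature_vector(g, trn$space))
    reduced <- predict(red$net, feature_vector(g, red$space))
    expect_lt(abs(full - reduced), 1e-9)
  }
  # a spec using codes outside the space errors
  spec_bad <- trn$spec
  spec_bad$chem$f_star <- c(spec_bad$chem$f_star, "(C0(C2))")
  expect_error(reduce_inputs(trn$net, trn$space, spec_bad), "absent")
})

test_that("serialization preserves predictions", {
  trn <- toy_training()
  f <- tempfile(fileext = ".json")
  write_mlp(trn$net, trn$space, f)
  back <- read_mlp(f)
  expect_equal(back$space$slot_names, trn$space$slot_names)
  x <- feature_matrix(trn$dataset, trn$space)
  expect_lt(max(abs(predict(back$net, x) - predict(trn$net, x))), 1e-9)
})
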