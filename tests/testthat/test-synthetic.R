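test_that("generation is reproducible given a seed", {
  cfg <- synthetic_config(n_graphs = 15L)
  ds1 <- generate_synthetic_dataset(cfg, seed = 77)
  ds2 <- generate_synthetic_dataset(cfg, seed = 77)
  f1 <- tempfile(fileext = ".sdf"); f2 <- tempfile(fileext = ".sdf")
  write_sdf(ds1$graphs, f1); write_sdf(ds2$graphs, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(ds1$values, ds2$values)
  ds3 <- generate_synthetic_dataset(cfg, seed = 78)
  expect_false(identical(readLines(f1), {
    f3 <- tempfile(fileext = ".sdf"); write_sdf(ds3$graphs, f3); readLines(f3)
  }))
})

test_that("generated graphs are valid and the interior matches the skeleton sizes", {
  cfg <- synthetic_config(n_interior = c(4L, 8L))
  ds <- generate_synthetic_dataset(cfg, seed = 15)
  for (g in ds$graphs[1:30]) {
    expect_s3_class(g, "chem_graph")        # construction enforces valences
    dec <- two_layer(g, cfg$rho)
    k <- length(dec$interior_vertices)
    expect_gte(k, 4L); expect_lte(k, 8L)
  }
})

test_that("the descriptor space over the output covers the configured elements", {
  cfg <- synthetic_config(elements = c("C", "N", "O"))
  ds <- generate_synthetic_dataset(cfg, seed = 16)
  sp <- build_descriptor_space(ds, cfg$rho)
  expect_setequal(union(sp$lambda_int, sp$lambda_ex), c("C", "N", "O"))
})

test_that("a noiseless linear ground truth is recovered by training", {
  cfg <- synthetic_config(noise_sd = 0, n_graphs = 70L)
  ds <- generate_synthetic_dataset(cfg, seed = 17)
  sp <- build_descriptor_space(ds, cfg$rho)
  net <- mlp_fit(ds, hidden = 16L, space = sp, seed = 2, epochs = 2500)
  expect_gte(net$r2_train, 0.99)
})
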