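test_that("chemical symbols, adjacency and edge configurations orient correctly", {
  g <- chem_graph(4, rbind(c(1, 2), c(2, 3), c(2, 4)),
                  c("O", "C", "C", "N"), c(1, 2, 1))
  expect_equal(chemical_symbol(g, 2), "C3")
  expect_equal(chemical_symbol(g, 1), "O1")
  expect_equal(adjacency_config(g, 1), "C,O,1")     # element order C < O
  expect_equal(adjacency_config(g, 2), "C,C,2")
  dec <- two_layer(g, 0)                            # everything interior
  expect_equal(edge_config(g, 2, dec), "C1,C3,2")
  dec1 <- two_layer(g, 1)
  expect_error(edge_config(g, 1, dec1), "interior")
  # orientation is stable under endpoint swap
  g2 <- cg_permute(g, c(2, 1, 3, 4))
  expect_equal(sort(adjacency_config(g2)), sort(adjacency_config(g)))
})

test_that("descriptor space cardinalities drive K", {
  tri <- chem_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)), rep("C", 3), rep(1, 3))
  sp <- build_descriptor_space(list(tri), 2)
  expect_equal(sp$lambda_int, "C")
  expect_length(sp$lambda_ex, 0L)
  expect_equal(sp$gamma_int, "C2,C2,1")
  expect_equal(sp$fringe_set, "(C0)")
  expect_equal(sp$K, 17L + 1L + 0L + 1L + 1L)
  expect_length(sp$slot_names, sp$K)
  # K always recomputable from the stored set sizes
  cfg <- synthetic_config()
  ds <- generate_synthetic_dataset(cfg, seed = 5)
  sp2 <- build_descriptor_space(ds, 2)
  expect_equal(sp2$K, 17L + length(sp2$lambda_int) + length(sp2$lambda_ex) +
                 length(sp2$gamma_int) + length(sp2$fringe_set))
})

test_that("feature vectors satisfy the conservation identities", {
  cfg <- synthetic_config()
  ds <- generate_synthetic_dataset(cfg, seed = 6)
  sp <- build_descriptor_space(ds, 2)
  sel <- function(fv, prefix) sum(fv[startsWith(names(fv), prefix)])
  for (g in ds$graphs[1:40]) {
    dec <- two_layer(g, 2)
    fv <- feature_vector(g, sp, dec)
    expect_equal(sel(fv, "na_int_"), unname(fv["n_int"]))
    expect_equal(sel(fv, "na_ex_"), unname(fv["n"] - fv["n_int"]))
    expect_equal(sel(fv, "ec_("), length(dec$interior_edges))
    expect_equal(sel(fv, "fc_"), unname(fv["n_int"]))
    expect_equal(sum(fv[paste0("dg_", 1:4)]), unname(fv["n_int"]))
    expect_equal(sum(fv[paste0("dg_int_", 1:4)]), unname(fv["n_int"]))
    expect_equal(sel(fv, "hydg_"), unname(fv["n"]))
    # mean mass surrogate is bracketed by the element masses present
    masses <- g$table$mass10[match(unique(g$alpha), g$table$symbol)]
    expect_gte(fv[["ms_avg"]], min(masses))
    expect_lte(fv[["ms_avg"]], max(masses))
  }
})

test_that("feature vectors are isomorphism invariants", {
  cfg <- synthetic_config()
  ds <- generate_synthetic_dataset(cfg, seed = 8)
  sp <- build_descriptor_space(ds, 2)
  set.seed(9)
  for (g in ds$graphs[1:10]) {
    h <- cg_permute(g, sample(g$n))
    expect_equal(feature_vector(h, sp), feature_vector(g, sp))
  }
})

test_that("an all-carbon graph has the carbon mass surrogate as its mean", {
  g <- chem_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), rep("C", 4), rep(1, 4))
  sp <- build_descriptor_space(list(g), 2)
  fv <- feature_vector(g, sp)
  expect_equal(unname(fv["ms_avg"]), floor(10 * 12.011))  # 120
  expect_equal(unname(fv["n"]), 4)
})

test_that("out-of-space graphs raise a structured error naming the code", {
  g_cn <- chem_graph(5, cbind(1:4, 2:5), c("C", "C", "N", "C", "C"), rep(1, 4))
  g_c <- chem_graph(5, cbind(1:4, 2:5), rep("C", 5), rep(1, 4))
  sp <- build_descriptor_space(list(g_c), 2)
  err <- tryCatch(feature_vector(g_cn, sp), moldesign_out_of_space = function(e) e)
  expect_s3_class(err, "moldesign_out_of_space")
  expect_true(length(err$missing) >= 1L)
})

test_that("feature CSV export keeps one named column per slot", {
  g <- chem_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), rep("C", 4), rep(1, 4))
  sp <- build_descriptor_space(list(g), 2)
  x <- feature_matrix(list(g), sp)
  f <- tempfile(fileext = ".csv")
  write_feature_csv(x, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(colnames(back), sp$slot_names)
  expect_equal(unlist(back[1, ], use.names = FALSE), unname(x[1, ]))
})
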