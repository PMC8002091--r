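test_that("leaf-stripping heights match the definition on canonical shapes", {
  p5 <- chem_graph(5, cbind(1:4, 2:5), rep("C", 5), rep(1, 4))
  expect_equal(height_map(p5), c(0, 1, Inf, 1, 0))
  cyc <- chem_graph(6, cbind(1:6, c(2:6, 1)), rep("C", 6), rep(1, 6))
  expect_true(all(is.infinite(height_map(cyc))))
})

test_that("decomposition partitions vertices and edges consistently", {
  cfg <- synthetic_config()
  set.seed(21)
  pool <- moldesign:::make_fringe_pool(cfg)
  for (rep in 1:30) {
    g <- random_chem_graph(cfg, pool)
    for (rho in 1:3) {
      orc <- oracle_partition(g, rho)
      dec <- tryCatch(two_layer(g, rho),
                      moldesign_empty_interior = function(e) NULL)
      if (is.null(dec)) {
        expect_length(orc$int, 0L)
        next
      }
      expect_equal(dec$interior_vertices, orc$int)
      expect_equal(dec$exterior_vertices, orc$ext)
      expect_equal(dec$exterior_edges, orc$ext_edges)
      expect_equal(sort(c(dec$interior_edges, dec$exterior_edges)),
                   seq_len(nrow(g$edges)))
      # core is always interior
      ce <- core_edges(g)
      expect_true(all(ce$edges %in% dec$interior_edges))
      expect_true(all(ce$vertices %in% dec$interior_vertices))
    }
  }
})

test_that("rho = 0 keeps everything interior and a short graph errors", {
  p2 <- chem_graph(2, rbind(c(1, 2)), c("C", "C"), 1)
  dec <- two_layer(p2, 0)
  expect_length(dec$exterior_vertices, 0L)
  expect_length(Filter(function(t) length(t$vids) > 1L, dec$fringe_trees), 0L)
  err <- tryCatch(two_layer(p2, 1), moldesign_empty_interior = function(e) e)
  expect_s3_class(err, "moldesign_empty_interior")
  expect_s3_class(err$data$graph, "chem_graph")
})

test_that("fringe trees cover the exterior exactly and respect the height cap", {
  cfg <- synthetic_config()
  set.seed(31)
  pool <- moldesign:::make_fringe_pool(cfg)
  for (rep in 1:15) {
    g <- random_chem_graph(cfg, pool)
    dec <- two_layer(g, 2)
    fts <- fringe_trees(dec)
    expect_length(fts, length(dec$interior_vertices))
    nonroots <- unlist(lapply(fts, function(t) t$vids[-1L]))
    expect_setequal(nonroots, dec$exterior_vertices)
    expect_true(all(vapply(fts, function(t) t$height <= 2L, logical(1))))
    expect_true(all(vapply(fts, function(t) t$root %in% dec$interior_vertices,
                           logical(1))))
    # reconstruction: interior edges plus fringe edges give back E(G)
    n_fringe_edges <- sum(vapply(fts, function(t) length(t$vids) - 1L, integer(1)))
    expect_equal(length(dec$interior_edges) + n_fringe_edges, nrow(g$edges))
  }
})

test_that("interior shrinks monotonically in rho and is idempotent", {
  cfg <- synthetic_config()
  set.seed(41)
  pool <- moldesign:::make_fringe_pool(cfg)
  for (rep in 1:10) {
    g <- random_chem_graph(cfg, pool)
    prev <- seq_len(g$n)
    for (rho in 0:3) {
      dec <- tryCatch(two_layer(g, rho), moldesign_empty_interior = function(e) NULL)
      if (is.null(dec)) break
      expect_true(all(dec$interior_vertices %in% prev))
      prev <- dec$interior_vertices
    }
  }
  # idempotence: when every fringe tree is trivial (no exterior at all),
  # decomposing again changes nothing
  cfg0 <- synthetic_config(lean = TRUE, p_fringe = 0)
  pool0 <- moldesign:::make_fringe_pool(cfg0)
  for (rep in 1:5) {
    g <- random_chem_graph(cfg0, pool0)
    dec <- two_layer(g, 2)
    expect_length(dec$exterior_vertices, 0L)
    sub <- moldesign:::subgraph_chem(g, dec$interior_vertices, dec$interior_edges)
    dec2 <- two_layer(sub, 2)
    expect_equal(length(dec2$interior_vertices), g$n)
  }
})

test_that("k-leanness matches the rooted and core-based definitions", {
  p5 <- chem_graph(5, cbind(1:4, 2:5), rep("C", 5), rep(1, 4))
  for (k in 0:3) expect_true(is_k_lean(p5, k))
  # spider with three legs of length 3 rooted at its center: three vertices
  # reach height 2, so it is not 2-lean
  sp <- chem_graph(10, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 5), c(5, 6),
                             c(6, 7), c(1, 8), c(8, 9), c(9, 10)),
                   rep("C", 10), rep(1, 9))
  expect_false(is_k_lean(sp, 2, root = 1))
  # cycle-skeleton constructions with height-capped fringes are 2-lean
  cfg <- synthetic_config(lean = TRUE)
  set.seed(51)
  pool <- moldesign:::make_fringe_pool(cfg)
  for (rep in 1:10) expect_true(is_k_lean(random_chem_graph(cfg, pool), 2))
})
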