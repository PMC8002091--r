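test_that("construction validates the chemical model", {
  g <- chem_graph(2, rbind(c(1, 2)), c("C", "C"), 1)
  expect_s3_class(g, "chem_graph")
  expect_equal(hydro_degree(g), c(3L, 3L))

  # an O with three single bonds violates its valence of 2
  expect_error(chem_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4)),
                          c("O", "C", "C", "C"), c(1, 1, 1)),
               "valence violation at vertex 1")
  expect_error(chem_graph(3, rbind(c(1, 2)), c("C", "C", "C"), 1), "connected")
  expect_error(chem_graph(2, rbind(c(1, 1)), c("C", "C"), 1), "loop")
  expect_error(chem_graph(2, rbind(c(1, 2), c(2, 1)), c("C", "C"), c(1, 1)), "parallel")
})

test_that("random labeled trees are accepted exactly when an independent recount passes", {
  set.seed(101)
  tab <- default_element_table()
  for (rep in 1:200) {
    n <- sample(2:10, 1)
    par <- vapply(2:n, function(j) sample.int(j - 1L, 1L), integer(1))
    edges <- cbind(par, 2:n)
    alpha <- sample(tab$symbol, n, replace = TRUE)
    beta <- sample(1:3, n - 1L, replace = TRUE)
    # independent recount of per-vertex bond sums
    bs <- integer(n)
    for (k in seq_len(n - 1L)) {
      bs[edges[k, 1L]] <- bs[edges[k, 1L]] + beta[k]
      bs[edges[k, 2L]] <- bs[edges[k, 2L]] + beta[k]
    }
    valid <- all(bs <= tab$valence[match(alpha, tab$symbol)])
    got <- tryCatch(chem_graph(n, edges, alpha, beta, tab), error = function(e) NULL)
    expect_equal(!is.null(got), valid)
    if (valid) {
      expect_equal(beta_sum(got), bs)
      expect_true(all(hydro_degree(got) >= 0))
    }
  }
})

test_that("handshake identity links hydro-degrees, valences and bonds", {
  cfg <- synthetic_config()
  set.seed(7)
  pool <- moldesign:::make_fringe_pool(cfg)
  for (rep in 1:25) {
    g <- random_chem_graph(cfg, pool)
    lhs <- sum(hydro_degree(g))
    rhs <- sum(elem_valence <- g$table$valence[match(g$alpha, g$table$symbol)]) -
      2 * sum(g$beta)
    expect_equal(lhs, rhs)
  }
})

test_that("graph rank counts independent cycles", {
  tree <- chem_graph(5, cbind(1:4, 2:5), rep("C", 5), rep(1, 4))
  expect_equal(graph_rank(tree), 0L)
  cyc <- chem_graph(5, cbind(1:5, c(2:5, 1)), rep("C", 5), rep(1, 5))
  expect_equal(graph_rank(cyc), 1L)
  # three cycles sharing edges: theta-like graph of rank 2
  theta <- chem_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)),
                      c("C", "C", "C", "C"), rep(1, 5))
  expect_equal(graph_rank(theta), 2L)
  # equals the out-of-spanning-tree edge count on random graphs
  cfg <- synthetic_config()
  set.seed(11)
  pool <- moldesign:::make_fringe_pool(cfg)
  for (rep in 1:10) {
    g <- random_chem_graph(cfg, pool)
    expect_equal(graph_rank(g), nrow(g$edges) - g$n + 1L)
  }
})

test_that("core edges follow the cycle-or-cycle-separating-bridge definition", {
  cyc <- chem_graph(5, cbind(1:5, c(2:5, 1)), rep("C", 5), rep(1, 5))
  expect_equal(core_edges(cyc)$edges, 1:5)
  tree <- chem_graph(5, cbind(1:4, 2:5), rep("C", 5), rep(1, 4))
  expect_length(core_edges(tree)$edges, 0L)
  # two triangles joined by a path: triangles and path edges are all core
  edges <- rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5), c(5, 6),
                 c(6, 7), c(7, 8), c(6, 8))
  tt <- chem_graph(8, edges, rep("C", 8), rep(1, 9))
  # oracle: an edge is core iff not a bridge, or a bridge with a cycle on
  # both sides (checked by rank of each side)
  oracle_core <- vapply(seq_len(nrow(edges)), function(k) {
    rest <- edges[-k, , drop = FALSE]
    comp <- integer(8); comp[edges[k, 1L]] <- 1L
    repeat {
      grew <- FALSE
      for (r in seq_len(nrow(rest))) {
        a <- rest[r, 1L]; b <- rest[r, 2L]
        if (comp[a] && !comp[b]) { comp[b] <- 1L; grew <- TRUE }
        if (comp[b] && !comp[a]) { comp[a] <- 1L; grew <- TRUE }
      }
      if (!grew) break
    }
    if (comp[edges[k, 2L]] == 1L) return(TRUE)   # in a cycle
    side1 <- which(comp == 1L); side2 <- which(comp == 0L)
    has_cycle <- function(vs) {
      ne <- sum(rest[, 1L] %in% vs & rest[, 2L] %in% vs)
      ne >= length(vs)
    }
    has_cycle(side1) && has_cycle(side2)
  }, logical(1))
  expect_equal(core_edges(tt)$edges, which(oracle_core))
  expect_equal(sort(core_edges(tt)$vertices), 1:8)
  # invariance under relabeling
  set.seed(3)
  perm <- sample(8)
  tt2 <- cg_permute(tt, perm)
  expect_equal(sort(perm[core_edges(tt)$vertices]), core_edges(tt2)$vertices)
})
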