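test_that("codes are invariant to vertex ids and child order", {
  t1 <- parse_fringe_code("(C0(O1)(O1))")
  # same tree entered with children swapped
  t2 <- structure(list(root = 1L, vids = 1:3, par = c(0L, 1L, 1L),
                       alpha = c("C", "O", "O"),
                       bond = c(NA, 1L, 1L), height = 1L),
                  class = "fringe_tree")
  expect_equal(canonical_code(t1), canonical_code(t2))
  single <- parse_fringe_code("(C0)")
  expect_equal(canonical_code(single), "(C0)")
})

test_that("parse is the inverse of the code on random trees", {
  set.seed(61)
  for (rep in 1:50) {
    t <- as_fringe(random_raw_tree(sample(2:8, 1)))
    code <- canonical_code(t)
    expect_equal(canonical_code(parse_fringe_code(code)), code)
  }
})

test_that("code equality agrees with the brute-force r-isomorphism oracle", {
  set.seed(71)
  trees <- replicate(120, as_fringe(random_raw_tree(sample(2:7, 1))),
                     simplify = FALSE)
  codes <- vapply(trees, canonical_code, character(1))
  # sample pairs, biased toward equal-size pairs where collisions can occur
  sizes <- vapply(trees, function(t) length(t$alpha), integer(1))
  for (rep in 1:300) {
    i <- sample.int(length(trees), 1)
    js <- which(sizes == sizes[i])
    j <- js[sample.int(length(js), 1)]
    expect_equal(codes[i] == codes[j], oracle_r_isomorphic(trees[[i]], trees[[j]]),
                 info = paste(codes[i], "vs", codes[j]))
  }
})

test_that("whole-graph certificates and isomorphism agree under relabeling", {
  cfg <- synthetic_config()
  set.seed(81)
  pool <- moldesign:::make_fringe_pool(cfg)
  for (rep in 1:10) {
    g <- random_chem_graph(cfg, pool)
    h <- cg_permute(g, sample(g$n))
    expect_true(cg_isomorphic(g, h))
    expect_equal(cg_certificate(g), cg_certificate(h))
    # perturbing one element label breaks both
    g2 <- g
    g2$alpha[1L] <- if (g$alpha[1L] == "C") "N" else "C"
    g2 <- tryCatch(chem_graph(g2$n, g2$edges, g2$alpha, g2$beta, g2$table),
                   error = function(e) NULL)
    if (!is.null(g2)) {
      expect_false(cg_isomorphic(g, g2))
      expect_false(cg_certificate(g) == cg_certificate(g2))
    }
  }
})
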