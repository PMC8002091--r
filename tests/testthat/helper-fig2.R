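# Text-reconstructed example molecule for the two-layered decomposition:
# an interior of 28 vertices built from a 12-vertex cyclic scaffold by
# subdividing five edges into the stated paths (one extra path vertex sits
# on a sixth, length-2 connection), attaching three leaf paths, and hanging
# eight fringe trees with 19 exterior vertices (14 stripped in round 0,
# 5 in round 1).  Connections among the scaffold vertices beyond the stated
# paths are chosen here (the source shows them only graphically); all counts
# are as stated.
fig2_graph <- function() {
  edges <- rbind(
    # subdivision paths
    c(1, 13), c(13, 2),                      # u1-u13-u2
    c(1, 14), c(14, 3),                      # u1-u14-u3
    c(4, 15), c(15, 16), c(16, 7),           # u4-u15-u16-u7
    c(10, 17), c(17, 18), c(18, 19), c(19, 11),   # u10-..-u11
    c(11, 20), c(20, 21), c(21, 22), c(22, 12),   # u11-..-u12
    c(9, 23), c(23, 10),                     # length-2 connection via u23
    # scaffold connections
    c(2, 4), c(3, 5), c(4, 5), c(5, 6), c(6, 7), c(7, 8), c(8, 9),
    c(7, 10), c(10, 12),
    # leaf paths
    c(5, 24),                                # Q at u5
    c(18, 25), c(25, 26), c(26, 27),         # Q at u18
    c(22, 28))                               # Q at u22
  n <- 28L
  # eight fringe trees: five with one height-1 vertex, three leaf-only
  fringe <- list(
    list(root = 24L, shape = c(2L)),   # root - mid - two leaves
    list(root = 27L, shape = c(1L)),
    list(root = 28L, shape = c(2L)),
    list(root = 1L,  shape = c(1L)),
    list(root = 6L,  shape = c(2L)),
    list(root = 8L,  shape = c(0L, 2L)),  # two direct leaves
    list(root = 9L,  shape = c(0L, 2L)),
    list(root = 11L, shape = c(0L, 2L)))
  for (ft in fringe) {
    if (ft$shape[1L] > 0L) {
      mid <- n + 1L
      edges <- rbind(edges, c(ft$root, mid))
      for (j in seq_len(ft$shape[1L])) edges <- rbind(edges, c(mid, n + 1L + j))
      n <- n + 1L + ft$shape[1L]
    } else {
      for (j in seq_len(ft$shape[2L])) edges <- rbind(edges, c(ft$root, n + j))
      n <- n + ft$shape[2L]
    }
  }
  chem_graph(n, edges, rep("C", n), rep(1L, nrow(edges)))
}
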