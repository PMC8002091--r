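# Independent brute-force oracles and shared fixtures.  Everything here is
# deliberately written from the definitions, not by calling the package's
# own implementation paths.

# --- fresh re-implementation of iterated leaf stripping --------------------
oracle_strip_heights <- function(n, edges) {
  ht <- rep(Inf, n)
  alive <- rep(TRUE, n)
  round <- 0L
  repeat {
    deg <- integer(n)
    for (k in seq_len(nrow(edges))) {
      u <- edges[k, 1L]; v <- edges[k, 2L]
      if (alive[u] && alive[v]) { deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L }
    }
    leaves <- which(alive & deg == 1L)
    if (!length(leaves)) break
    ht[leaves] <- round
    alive[leaves] <- FALSE
    round <- round + 1L
  }
  ht
}

# two-layer partition recomputed from scratch
oracle_partition <- function(g, rho) {
  ht <- oracle_strip_heights(g$n, g$edges)
  ext <- which(ht < rho)
  list(ext = ext, int = setdiff(seq_len(g$n), ext),
       ext_edges = which((g$edges[, 1L] %in% ext) | (g$edges[, 2L] %in% ext)))
}

# --- brute-force root-preserving isomorphism of labeled rooted trees -------
# trees are fringe_tree-like lists (par, alpha, bond, root first)
oracle_r_isomorphic <- function(t1, t2) {
  n <- length(t1$alpha)
  if (n != length(t2$alpha)) return(FALSE)
  ch1 <- vector("list", n); ch2 <- vector("list", n)
  for (j in seq_len(n)[-1L]) {
    ch1[[t1$par[j]]] <- c(ch1[[t1$par[j]]], j)
    ch2[[t2$par[j]]] <- c(ch2[[t2$par[j]]], j)
  }
  match_node <- function(a, b) {
    if (t1$alpha[a] != t2$alpha[b]) return(FALSE)
    k1 <- ch1[[a]]; k2 <- ch2[[b]]
    if (length(k1) != length(k2)) return(FALSE)
    if (!length(k1)) return(TRUE)
    # try every bijection between children
    try_perm <- function(rem1, rem2) {
      if (!length(rem1)) return(TRUE)
      a1 <- rem1[1L]
      for (j in seq_along(rem2)) {
        b1 <- rem2[j]
        if (t1$bond[a1] == t2$bond[b1] && match_node(a1, b1) &&
            try_perm(rem1[-1L], rem2[-j])) return(TRUE)
      }
      FALSE
    }
    try_perm(k1, k2)
  }
  match_node(1L, 1L)
}

# random labeled rooted tree as raw parent arrays (valence-valid not required)
random_raw_tree <- function(n, elements = c("C", "O", "N"), mults = 1:2) {
  par <- c(0L, vapply(seq_len(n - 1L) + 1L, function(j) sample.int(j - 1L, 1L), integer(1)))
  list(root = 1L, vids = seq_len(n), par = par,
       alpha = sample(elements, n, replace = TRUE),
       bond = c(NA_integer_, sample(mults, n - 1L, replace = TRUE)))
}

as_fringe <- function(t) {
  depth <- integer(length(t$par))
  for (j in seq_along(t$par)[-1L]) depth[j] <- depth[t$par[j]] + 1L
  structure(c(t, list(height = max(depth))), class = "fringe_tree")
}

# --- shared fixtures -------------------------------------------------------
toy_fringe_codes <- function() {
  c("(C0)", "(N0)", "(O0)",
    "(C0(C1(C1)))", "(C0(O1(C1)))", "(N0(C1(C1)))", "(C0(N1(C1)))")
}

# tiny monocyclic specification (two seed vertices joined by two paths)
toy_spec <- function(n_star = 14L, n_int = c(3L, 5L), l_ub = c(3L, 2L),
                     gamma = NULL, fringe = toy_fringe_codes(),
                     lambda = c("C", "N", "O"), ...) {
  tab <- default_element_table()
  if (is.null(gamma)) gamma <- all_edge_configs(lambda, tab)
  sg <- seed_graph(2, rbind(c(1, 2), c(1, 2)), c("ge2", "ge1"))
  target_spec(sg, rho = 2, n_star = n_star, n_lb = 4,
              n_int_lb = n_int[1L], n_int_ub = n_int[2L],
              interior = list(l_lb = c(2, 1), l_ub = l_ub,
                              v_ch_ub = 2L, bl_ub = 1L, ch_ub = 1L),
              chem = list(lambda_int = lambda, gamma_int = gamma,
                          fringe_e = fringe), ...)
}

# dataset of witnesses of a spec plus a noiseless linear property
toy_training <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec0 <- toy_spec()
    set.seed(424)
    ws <- list()
    tries <- 0L
    while (length(ws) < 36L && tries < 300L) {
      tries <- tries + 1L
      g <- random_extension(spec0)
      if (!is.null(g)) ws[[length(ws) + 1L]] <- g
    }
    cfg <- synthetic_config(noise_sd = 0)
    ds <- chem_dataset(ws, vapply(ws, synthetic_property, numeric(1), cfg = cfg))
    space <- build_descriptor_space(ds, 2L)
    spec <- toy_spec(gamma = space$gamma_int,
                     fringe = intersect(toy_fringe_codes(), space$fringe_set))
    net <- mlp_fit(ds, hidden = 8L, space = space, seed = 3L, epochs = 2500L)
    red <- reduce_inputs(net, space, spec)
    cache <<- list(spec0 = spec0, spec = spec, dataset = ds, space = space,
                   net = net, rnet = red$net, rspace = red$space)
    cache
  }
})

# deterministic pool of many distinct valence-valid fringe classes
# (canonical codes, height <= 2) for the wide descriptor spaces
many_fringe_codes <- function(k) {
  elements <- c("C", "N", "O")
  out <- character(0)
  for (a in elements) out <- c(out, sprintf("(%s0)", a))
  for (a in c("C", "N")) for (b in elements) for (m in 1:2) {
    out <- c(out, sprintf("(%s0(%s%d))", a, b, m))
  }
  for (a in c("C", "N")) for (b in c("C", "N")) for (cc in elements) {
    for (m1 in 1:2) for (m2 in 1:2) {
      out <- c(out, sprintf("(%s0(%s%d(%s%d)))", a, b, m1, cc, m2))
    }
  }
  for (b in c("C", "N")) for (cc in elements) for (d in elements) {
    out <- c(out, sprintf("(C0(%s1(%s1)(%s1)))", b, cc, d))
    out <- c(out, sprintf("(C0(%s1(%s1))(%s1))", b, cc, d))
  }
  for (a in c("C", "N")) for (b in elements) for (cc in elements) {
    out <- c(out, sprintf("(%s0(%s1)(%s1))", a, b, cc))
  }
  for (b in c("C", "N")) for (cc in elements) for (d in elements) for (e in elements) {
    out <- c(out, sprintf("(C0(%s1(%s1)(%s1))(%s1))", b, cc, d, e))
  }
  tab <- default_element_table()
  codes <- character(0)
  for (cd in out) {
    s <- tryCatch(moldesign:::ft_summary(parse_fringe_code(cd), tab),
                  error = function(e) NULL)
    if (!is.null(s)) codes <- c(codes, s$code)
  }
  codes <- unique(codes)
  stopifnot(length(codes) >= k)
  codes[seq_len(k)]
}
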