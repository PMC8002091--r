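#' Configuration for the synthetic fixture generator
#'
#' The generator emulates hydrogen-suppressed organic molecules as seen by the
#' two-layered model: a connected interior skeleton of bounded cycle rank with
#' elements assigned under the valence condition, and height-bounded fringe
#' trees hanging from interior vertices.  Property values follow a stated
#' linear ground truth over descriptor slots plus Gaussian noise, so the whole
#' train-and-invert pipeline is exercisable offline.
#'
#' @param elements element symbols to use (must be in \code{table}).
#' @param rho branch-parameter.
#' @param n_interior integer range (length 2) for the interior vertex count.
#' @param rank integer range for the cycle rank of the skeleton.
#' @param n_graphs dataset size.
#' @param pool_size number of distinct random fringe trees in the candidate pool.
#' @param fringe_max_nodes maximum vertex count of a pooled fringe tree.
#' @param p_fringe probability of attaching a nontrivial fringe tree to an
#'   interior vertex that does not require one.
#' @param p_multi probability of raising an interior bond above single.
#' @param coef named numeric vector: linear ground-truth coefficients over
#'   descriptor slot names (fixed slots and \code{na_int_}/\code{na_ex_} counts).
#' @param intercept ground-truth intercept.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param lean if \code{TRUE}, use a cycle skeleton with fringes only on core
#'   vertices, which guarantees 2-lean output.
#' @param table an \code{\link{element_table}}.
#' @return list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(elements = c("C", "N", "O"), rho = 2L,
                             n_interior = c(4L, 10L), rank = c(0L, 2L),
                             n_graphs = 120L, pool_size = 8L,
                             fringe_max_nodes = 4L, p_fringe = 0.6,
                             p_multi = 0.2,
                             coef = c(n = 1.5, n_int = -0.8, ms_avg = 0.05,
                                      bd_int_2 = 3, na_int_O = -1.2),
                             intercept = 20, noise_sd = 0.1,
                             lean = FALSE,
                             table = default_element_table()) {
  stopifnot(all(elements %in% table$symbol), rho >= 1L,
            n_interior[1L] >= 2L, n_interior[2L] >= n_interior[1L])
  structure(list(elements = elements, rho = as.integer(rho),
                 n_interior = as.integer(n_interior), rank = as.integer(rank),
                 n_graphs = as.integer(n_graphs), pool_size = as.integer(pool_size),
                 fringe_max_nodes = as.integer(fringe_max_nodes),
                 p_fringe = p_fringe, p_multi = p_multi,
                 coef = coef, intercept = intercept, noise_sd = noise_sd,
                 lean = isTRUE(lean), table = table),
            class = "synthetic_config")
}

# size-safe scalar draw (sample() treats a scalar as 1:x)
sample1 <- function(x) x[sample.int(length(x), 1L)]

# a path of length exactly rho hanging below a root of element `elem`
path_fringe <- function(elem, rho, elements, table) {
  vals <- elem_valence(table, elements)
  inner <- elements[vals >= 2L]
  alpha <- c(elem, sample(inner, rho - 1L, replace = TRUE), sample(elements, 1L))
  structure(list(root = 1L, vids = seq_len(rho + 1L),
                 par = c(0L, seq_len(rho)),
                 alpha = alpha,
                 bond = c(NA_integer_, rep(1L, rho)),
                 height = as.integer(rho)),
            class = "fringe_tree")
}

# random valence-valid rooted tree of height <= rho
random_fringe_tree <- function(elements, rho, max_nodes, table) {
  alpha <- sample(elements, 1L)
  par <- 0L; bond <- NA_integer_; depth <- 0L
  spare <- elem_valence(table, alpha)   # root keeps no reserve here
  i <- 1L
  while (i <= length(alpha) && length(alpha) < max_nodes) {
    if (depth[i] < rho) {
      nkids <- sample(0:2, 1L, prob = c(0.4, 0.45, 0.15))
      for (k in seq_len(nkids)) {
        if (length(alpha) >= max_nodes) break
        m <- sample(1:2, 1L, prob = c(0.85, 0.15))
        if (spare[i] < m) next
        cand <- elements[elem_valence(table, elements) >= m]
        if (!length(cand)) next
        a <- sample(cand, 1L)
        alpha <- c(alpha, a); par <- c(par, i); bond <- c(bond, m)
        depth <- c(depth, depth[i] + 1L)
        spare[i] <- spare[i] - m
        spare <- c(spare, elem_valence(table, a) - m)
      }
    }
    i <- i + 1L
  }
  structure(list(root = 1L, vids = seq_along(alpha), par = par,
                 alpha = alpha, bond = bond,
                 height = max(depth)),
            class = "fringe_tree")
}

# fringe candidate pool: trivial tree and a height-rho path per element,
# plus random trees
make_fringe_pool <- function(cfg) {
  pool <- list()
  for (a in cfg$elements) {
    pool[[length(pool) + 1L]] <- parse_fringe_code(sprintf("(%s0)", a))
    if (elem_valence(cfg$table, a) >= 2L) {
      pool[[length(pool) + 1L]] <- path_fringe(a, cfg$rho, cfg$elements, cfg$table)
    }
  }
  tries <- 0L
  while (length(pool) < length(cfg$elements) + cfg$pool_size && tries < 200L) {
    t <- random_fringe_tree(cfg$elements, cfg$rho, cfg$fringe_max_nodes, cfg$table)
    codes <- vapply(pool, canonical_code, character(1))
    if (!(canonical_code(t) %in% codes)) pool[[length(pool) + 1L]] <- t
    tries <- tries + 1L
  }
  pool
}

#' Draw one random valence-valid connected chemical graph
#'
#' Builds a random connected interior skeleton (tree plus \code{rank} extra
#' edges, cycle if \code{lean}), assigns elements and bond multiplicities
#' respecting valences, and attaches fringe trees from a candidate pool.
#' Every skeleton vertex of interior degree at most 1 receives a fringe tree
#' of height exactly \code{rho}, which guarantees that the two-layered
#' decomposition at \code{rho} recovers the skeleton as the interior.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param pool optional fringe pool from \code{make_fringe_pool}.
#' @return a \code{\link{chem_graph}}.
#' @export
random_chem_graph <- function(cfg, pool = NULL) {
  if (is.null(pool)) pool <- make_fringe_pool(cfg)
  table <- cfg$table
  vals <- elem_valence(table, cfg$elements)
  k <- sample1(seq(cfg$n_interior[1L], cfg$n_interior[2L]))
  if (cfg$lean) {
    k <- max(k, 3L)
    edges <- cbind(seq_len(k), c(seq_len(k)[-1L], 1L))   # cycle skeleton
  } else {
    edges <- matrix(integer(0), ncol = 2L)
    deg <- integer(k)
    for (i in seq_len(k)[-1L]) {
      cand <- which(deg[seq_len(i - 1L)] < 4L)
      p <- cand[sample.int(length(cand), 1L)]
      edges <- rbind(edges, c(p, i))
      deg[p] <- deg[p] + 1L; deg[i] <- deg[i] + 1L
    }
    r <- sample1(seq(cfg$rank[1L], cfg$rank[2L]))
    for (j in seq_len(r)) {
      free <- which(deg < 4L)
      if (length(free) < 2L) break
      pair <- sample(free, 2L)
      key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
      if (paste(min(pair), max(pair)) %in% key) next
      edges <- rbind(edges, pair)
      deg[pair] <- deg[pair] + 1L
    }
  }
  deg <- tabulate(as.integer(edges), k)
  # element per skeleton vertex; degree-<=1 vertices need spare for a fringe
  alpha <- character(k)
  for (v in seq_len(k)) {
    need <- deg[v] + if (deg[v] <= 1L) 1L else 0L
    cand <- cfg$elements[vals >= need]
    if (!length(cand)) cand <- cfg$elements[vals == max(vals)]
    alpha[v] <- sample(cand, 1L)
  }
  beta <- rep(1L, nrow(edges))
  spare <- elem_valence(table, alpha) - deg
  reserve <- ifelse(deg <= 1L, 1L, 0L)   # room for the mandatory fringe root bond
  for (e in sample(seq_len(nrow(edges)))) {
    if (stats::runif(1) < cfg$p_multi) {
      u <- edges[e, 1L]; v <- edges[e, 2L]
      if (spare[u] - reserve[u] >= 1L && spare[v] - reserve[v] >= 1L) {
        beta[e] <- 2L
        spare[u] <- spare[u] - 1L; spare[v] <- spare[v] - 1L
      }
    }
  }
  # fringe assignment
  pool_code <- vapply(pool, canonical_code, character(1))
  pool_sum <- lapply(pool, ft_summary, table = table)
  chosen <- vector("list", k)
  for (v in seq_len(k)) {
    mandatory <- deg[v] <= 1L
    ok <- vapply(pool_sum, function(s) {
      s$root_elem == alpha[v] && s$root_beta <= spare[v] &&
        (!mandatory || s$height == cfg$rho) && (mandatory || s$height <= cfg$rho)
    }, logical(1))
    if (mandatory && !any(ok)) stop("internal error: no mandatory fringe available")
    if (!mandatory && (!any(ok) || stats::runif(1) > cfg$p_fringe)) {
      chosen[v] <- list(NULL)
    } else {
      pick <- which(ok)[sample.int(sum(ok), 1L)]
      if (pool_sum[[pick]]$nv_ex == 0L) chosen[v] <- list(NULL) else {
        chosen[[v]] <- pool[[pick]]
        spare[v] <- spare[v] - pool_sum[[pick]]$root_beta
      }
    }
  }
  assemble_graph(k, edges, alpha, beta, chosen, table)
}

# glue interior skeleton and per-vertex fringe templates into a chem_graph
assemble_graph <- function(k, edges, alpha, beta, fringes, table) {
  all_alpha <- alpha
  all_edges <- edges
  all_beta <- beta
  nv <- k
  for (v in seq_len(k)) {
    t <- fringes[[v]]
    if (is.null(t) || length(t$vids) == 1L) next
    idx <- c(v, nv + seq_len(length(t$vids) - 1L))
    for (j in seq_along(t$vids)[-1L]) {
      all_edges <- rbind(all_edges, c(idx[t$par[j]], idx[j]))
      all_beta <- c(all_beta, t$bond[j])
    }
    all_alpha <- c(all_alpha, t$alpha[-1L])
    nv <- nv + length(t$vids) - 1L
  }
  chem_graph(nv, all_edges, all_alpha, all_beta, table)
}

# named descriptor values needed by the ground-truth linear form,
# computed directly (no descriptor space required)
property_descriptors <- function(g, rho, names_needed) {
  dec <- two_layer(g, rho)
  int <- dec$interior_vertices
  out <- numeric(length(names_needed)); names(out) <- names_needed
  deg <- cg_degrees(g)
  hyd <- hydro_degree(g)
  for (nm in names_needed) {
    if (nm == "n") out[nm] <- g$n
    else if (nm == "n_int") out[nm] <- length(int)
    else if (nm == "ms_avg") out[nm] <- sum(elem_mass10(g$table, g$alpha)) / g$n
    else if (grepl("^dg_int_", nm)) {
      d <- as.integer(sub("^dg_int_", "", nm))
      ideg <- integer(g$n)
      for (kk in dec$interior_edges) {
        ideg[g$edges[kk, 1L]] <- ideg[g$edges[kk, 1L]] + 1L
        ideg[g$edges[kk, 2L]] <- ideg[g$edges[kk, 2L]] + 1L
      }
      out[nm] <- sum(ideg[int] == d)
    } else if (grepl("^dg_", nm)) {
      out[nm] <- sum(deg[int] == as.integer(sub("^dg_", "", nm)))
    } else if (grepl("^hydg_", nm)) {
      out[nm] <- sum(hyd == as.integer(sub("^hydg_", "", nm)))
    } else if (grepl("^bd_int_", nm)) {
      out[nm] <- sum(g$beta[dec$interior_edges] == as.integer(sub("^bd_int_", "", nm)))
    } else if (grepl("^na_int_", nm)) {
      out[nm] <- sum(g$alpha[int] == sub("^na_int_", "", nm))
    } else if (grepl("^na_ex_", nm)) {
      out[nm] <- sum(g$alpha[dec$exterior_vertices] == sub("^na_ex_", "", nm))
    } else stop("unsupported ground-truth coefficient name: ", nm)
  }
  out
}

#' Ground-truth property value of a graph under a synthetic configuration
#'
#' @param g a \code{\link{chem_graph}}.
#' @param cfg a \code{\link{synthetic_config}}.
#' @param noise if \code{TRUE} add the configured Gaussian noise.
#' @return numeric value.
#' @export
synthetic_property <- function(g, cfg, noise = FALSE) {
  x <- property_descriptors(g, cfg$rho, names(cfg$coef))
  y <- cfg$intercept + sum(cfg$coef * x[names(cfg$coef)])
  if (noise && cfg$noise_sd > 0) y <- y + stats::rnorm(1L, sd = cfg$noise_sd)
  y
}

#' Generate a reproducible synthetic dataset
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param seed integer seed; all randomness in generation flows through it.
#' @return a \code{\link{chem_dataset}} with attribute \code{"pool"} (the
#'   fringe candidate pool) and \code{"config"}.
#' @export
generate_synthetic_dataset <- function(cfg, seed = 1L) {
  set.seed(seed)
  pool <- make_fringe_pool(cfg)
  graphs <- vector("list", cfg$n_graphs)
  values <- numeric(cfg$n_graphs)
  for (i in seq_len(cfg$n_graphs)) {
    graphs[[i]] <- random_chem_graph(cfg, pool)
    values[i] <- synthetic_property(graphs[[i]], cfg, noise = TRUE)
  }
  ds <- chem_dataset(graphs, values, "synthetic")
  attr(ds, "pool") <- pool
  attr(ds, "config") <- cfg
  ds
}
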