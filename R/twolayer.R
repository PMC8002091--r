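#' Leaf-stripping heights
#'
#' Repeatedly delete all degree-1 vertices (never a designated root).  A vertex
#' removed in round \code{k} has height \code{k}; vertices that survive every
#' round (cycle cores, path centers, roots) carry the sentinel \code{Inf}.
#'
#' @param g a \code{\link{chem_graph}}.
#' @param roots optional vertex ids that are never stripped.
#' @return numeric vector of heights (with \code{Inf} sentinels).
#' @export
height_map <- function(g, roots = integer(0)) {
  ht <- rep(Inf, g$n)
  deg <- cg_degrees(g)
  alive <- rep(TRUE, g$n)
  is_root <- rep(FALSE, g$n); is_root[roots] <- TRUE
  adj <- cg_adjacency(g)
  round <- 0L
  repeat {
    leaves <- which(alive & !is_root & deg == 1L)
    if (!length(leaves)) break
    ht[leaves] <- round
    alive[leaves] <- FALSE
    for (v in leaves) {
      nb <- adj[[v]][, 1L]
      nb <- nb[alive[nb]]
      deg[nb] <- deg[nb] - 1L
    }
    round <- round + 1L
  }
  ht
}

#' Two-layered decomposition of a chemical graph
#'
#' For a branch-parameter \code{rho >= 0}, a vertex is an exterior vertex when
#' its leaf-stripping height is below \code{rho}, and an edge is exterior when
#' it is incident to an exterior vertex.  The exterior edges form a collection
#' of trees, each rooted at its unique highest vertex (an interior vertex);
#' every interior vertex owns exactly one fringe tree, possibly the trivial
#' single-vertex tree.  Every core vertex and core edge is interior.
#'
#' @param g a \code{\link{chem_graph}}.
#' @param rho non-negative integer branch-parameter.
#' @return An object of class \code{"two_layer"} with fields \code{rho},
#'   \code{ht}, \code{interior_vertices}, \code{exterior_vertices},
#'   \code{interior_edges}, \code{exterior_edges} (edge row indices) and
#'   \code{fringe_trees} (one per interior vertex, roots in increasing order).
#'   If every vertex is exterior an error of class
#'   \code{"moldesign_empty_interior"} is signalled; its \code{data} field
#'   carries the whole graph as one rooted tree.
#' @export
two_layer <- function(g, rho) {
  rho <- as.integer(rho)
  stopifnot(rho >= 0L)
  ht <- height_map(g)
  ext <- which(ht < rho)
  int <- which(ht >= rho)
  if (!length(int)) {
    root <- which.max(replace(ht, is.infinite(ht), g$n))  # highest vertex
    cond <- structure(
      class = c("moldesign_empty_interior", "error", "condition"),
      list(message = sprintf("empty interior: every vertex has height < rho = %d", rho),
           call = sys.call(-1),
           data = list(graph = g, ht = ht)))
    stop(cond)
  }
  m <- nrow(g$edges)
  is_ext_edge <- logical(m)
  if (m) {
    is_ext_edge <- (g$edges[, 1L] %in% ext) | (g$edges[, 2L] %in% ext)
  }
  # parent of each exterior vertex: its unique neighbor of larger height
  adj <- cg_adjacency(g)
  parent <- rep(NA_integer_, g$n)
  for (v in ext) {
    nb <- adj[[v]][, 1L]
    up <- nb[ht[nb] > ht[v]]
    if (length(up) != 1L) stop("internal error: exterior vertex without unique parent")
    parent[v] <- up
  }
  root_of <- function(v) {
    while (ht[v] < rho) v <- parent[v]
    v
  }
  groups <- vector("list", length(int))
  names(groups) <- as.character(int)
  for (v in ext) {
    r <- as.character(root_of(v))
    groups[[r]] <- c(groups[[r]], v)
  }
  fts <- vector("list", length(int))
  for (i in seq_along(int)) {
    r <- int[i]
    members <- groups[[as.character(r)]]
    fts[[i]] <- build_fringe_tree(g, r, members, parent, ht)
  }
  structure(list(rho = rho, ht = ht, graph = g,
                 interior_vertices = int, exterior_vertices = ext,
                 interior_edges = which(!is_ext_edge),
                 exterior_edges = which(is_ext_edge),
                 fringe_trees = fts),
            class = "two_layer")
}

# assemble a fringe_tree object from a root and its exterior members
build_fringe_tree <- function(g, root, members, parent, ht) {
  if (!length(members)) {
    return(structure(list(root = root, vids = root, par = 0L,
                          alpha = g$alpha[root], bond = NA_integer_,
                          height = 0L),
                     class = "fringe_tree"))
  }
  members <- members[order(-ht[members], members)]  # parents before children
  vids <- c(root, members)
  idx <- match(vids, vids)
  par <- c(0L, match(parent[members], vids))
  bond <- rep(NA_integer_, length(vids))
  ekey <- paste(g$edges[, 1L], g$edges[, 2L])
  for (j in seq_along(members)) {
    u <- members[j]; p <- parent[u]
    k <- which((g$edges[, 1L] == pmin(u, p)) & (g$edges[, 2L] == pmax(u, p)))
    bond[j + 1L] <- g$beta[k]
  }
  depth <- integer(length(vids))
  for (j in seq_along(vids)[-1L]) depth[j] <- depth[par[j]] + 1L
  structure(list(root = root, vids = vids, par = par,
                 alpha = g$alpha[vids], bond = bond,
                 height = max(depth)),
            class = "fringe_tree")
}

#' @export
print.two_layer <- function(x, ...) {
  nt <- sum(vapply(x$fringe_trees, function(t) length(t$vids) > 1L, logical(1)))
  cat(sprintf("two_layer (rho = %d): %d interior / %d exterior vertices, %d nontrivial fringe trees\n",
              x$rho, length(x$interior_vertices), length(x$exterior_vertices), nt))
  invisible(x)
}

#' Fringe trees of a decomposition
#'
#' @param dec a \code{\link{two_layer}} decomposition.
#' @param nontrivial if \code{TRUE}, drop single-vertex trees.
#' @return list of \code{"fringe_tree"} objects.
#' @export
fringe_trees <- function(dec, nontrivial = FALSE) {
  fts <- dec$fringe_trees
  if (nontrivial) fts <- Filter(function(t) length(t$vids) > 1L, fts)
  fts
}

#' @export
print.fringe_tree <- function(x, ...) {
  cat(sprintf("fringe_tree rooted at %d: %d vertices, height %d, code %s\n",
              x$root, length(x$vids), x$height, canonical_code(x)))
  invisible(x)
}

#' Test k-leanness
#'
#' A rooted tree is k-lean when at most one of its vertices is removed in
#' round \code{k} of leaf stripping (a "leaf k-branch").  A cyclic graph is
#' k-lean when each of the trees hanging off its core (the components induced
#' by non-core edges, rooted at their core vertex) is k-lean.  For an unrooted
#' acyclic graph the test asks whether some choice of root makes the tree
#' k-lean.
#'
#' @param g a \code{\link{chem_graph}}.
#' @param k non-negative integer.
#' @param root optional root vertex forcing the rooted-tree test.
#' @return logical.
#' @export
is_k_lean <- function(g, k, root = NULL) {
  k <- as.integer(k)
  if (!is.null(root)) {
    ht <- height_map(g, roots = root)
    return(sum(ht == k) <= 1L)
  }
  if (graph_rank(g) == 0L) {
    return(any(vapply(seq_len(g$n), function(r) {
      sum(height_map(g, roots = r) == k) <= 1L
    }, logical(1))))
  }
  ce <- core_edges(g)
  keep <- setdiff(seq_len(nrow(g$edges)), ce$edges)
  if (!length(keep)) return(TRUE)
  # components of the non-core forest, each rooted at its unique core vertex
  sub_edges <- g$edges[keep, , drop = FALSE]
  verts <- sort(unique(as.integer(sub_edges)))
  comp_ig <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  comp_ig <- igraph::add_edges(comp_ig, match(as.integer(t(sub_edges)), verts))
  comp <- igraph::components(comp_ig)
  for (ci in seq_len(comp$no)) {
    cv <- verts[comp$membership == ci]
    r <- intersect(cv, ce$vertices)
    if (length(r) != 1L) stop("internal error: pendant tree without unique core root")
    rows <- keep[(g$edges[keep, 1L] %in% cv) & (g$edges[keep, 2L] %in% cv)]
    sg <- subgraph_chem(g, cv, rows)
    ht <- height_map(sg, roots = match(r, cv))
    if (sum(ht == k) > 1L) return(FALSE)
  }
  TRUE
}

# induced subgraph on given vertices / edge rows, without validity re-checks
subgraph_chem <- function(g, vids, rows) {
  structure(list(n = length(vids),
                 edges = matrix(match(g$edges[rows, , drop = FALSE], vids),
                                ncol = 2L),
                 alpha = g$alpha[vids],
                 beta = g$beta[rows],
                 table = g$table),
            class = "chem_graph")
}
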