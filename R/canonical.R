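#' Canonical code of a chemical rooted tree
#'
#' Two chemical rooted trees get the same code exactly when they are
#' r-isomorphic: some bijection maps root to root and preserves element labels
#' and bond multiplicities.  The code is a recursive minimal string: each node
#' contributes \code{"(" <element> <bond-to-parent>} followed by its children's
#' codes sorted lexicographically, then \code{")"}.  The root's bond token is
#' fixed to \code{0}, so codes are parseable back into trees with
#' \code{\link{parse_fringe_code}}.
#'
#' @param t a \code{"fringe_tree"} (root-first parent-array representation).
#' @return character scalar.
#' @examples
#' tr <- parse_fringe_code("(C0(O1)(O2))")
#' canonical_code(tr)
#' @export
canonical_code <- function(t) {
  nv <- length(t$vids)
  children <- vector("list", nv)
  for (j in seq_len(nv)[-1L]) {
    p <- t$par[j]
    children[[p]] <- c(children[[p]], j)
  }
  rec <- function(i, bond_tok) {
    kids <- children[[i]]
    if (length(kids)) {
      sub <- vapply(kids, function(k) rec(k, t$bond[k]), character(1))
      inner <- paste(sort(sub, method = "radix"), collapse = "")
    } else inner <- ""
    paste0("(", t$alpha[i], bond_tok, inner, ")")
  }
  rec(1L, "0")
}

#' Parse a canonical fringe-tree code back into a rooted tree
#'
#' Inverse of \code{\link{canonical_code}} (up to child order, which is
#' canonical in the code).  Useful for materializing candidate fringe trees
#' written as code strings in a target specification.
#'
#' @param code character scalar such as \code{"(C0(N1)(O2))"}.
#' @return A \code{"fringe_tree"} with local ids (root is vertex 1).
#' @export
parse_fringe_code <- function(code) {
  chars <- strsplit(code, "")[[1]]
  pos <- 1L
  alpha <- character(0); par <- integer(0); bond <- integer(0)
  parse_node <- function(parent_idx) {
    if (chars[pos] != "(") stop("malformed code at position ", pos)
    pos <<- pos + 1L
    elem <- chars[pos]; pos <<- pos + 1L
    while (pos <= length(chars) && grepl("[a-z]", chars[pos])) {
      elem <- paste0(elem, chars[pos]); pos <<- pos + 1L
    }
    b <- as.integer(chars[pos]); pos <<- pos + 1L
    alpha <<- c(alpha, elem)
    par <<- c(par, parent_idx)
    bond <<- c(bond, if (parent_idx == 0L) NA_integer_ else b)
    me <- length(alpha)
    while (pos <= length(chars) && chars[pos] == "(") parse_node(me)
    if (pos > length(chars) || chars[pos] != ")") stop("malformed code: missing ')'")
    pos <<- pos + 1L
    me
  }
  parse_node(0L)
  nv <- length(alpha)
  depth <- integer(nv)
  for (j in seq_len(nv)[-1L]) depth[j] <- depth[par[j]] + 1L
  structure(list(root = 1L, vids = seq_len(nv), par = par,
                 alpha = alpha, bond = bond, height = max(depth)),
            class = "fringe_tree")
}

# --- summaries of a fringe-tree template used by descriptors and the MILP ---

ft_children <- function(t) {
  ch <- vector("list", length(t$vids))
  for (j in seq_along(t$vids)[-1L]) ch[[t$par[j]]] <- c(ch[[t$par[j]]], j)
  ch
}

# per-vertex bond sums within the tree (root excludes its interior bonds)
ft_beta_sums <- function(t) {
  bs <- integer(length(t$vids))
  for (j in seq_along(t$vids)[-1L]) {
    bs[j] <- bs[j] + t$bond[j]
    bs[t$par[j]] <- bs[t$par[j]] + t$bond[j]
  }
  bs
}

ft_summary <- function(t, table) {
  ch <- ft_children(t)
  bs <- ft_beta_sums(t)
  nonroot <- seq_along(t$vids)[-1L]
  val <- elem_valence(table, t$alpha)
  if (any(bs > val)) stop("fringe tree violates the valence condition")
  hyd <- val - bs   # root entry lacks interior bonds; exterior entries final
  list(code = canonical_code(t),
       nv_ex = length(t$vids) - 1L,
       root_elem = t$alpha[1L],
       root_deg = length(ch[[1L]]),
       root_beta = bs[1L],
       mass_ex = if (length(nonroot)) sum(elem_mass10(table, t$alpha[nonroot])) else 0L,
       na_ex = table(factor(t$alpha[nonroot], levels = unique(t$alpha[nonroot]))),
       hyd_ex = hyd[nonroot],
       deg_ex = vapply(nonroot, function(j) length(ch[[j]]) + 1L, integer(1)),
       height = t$height)
}

# --- whole-graph isomorphism and canonical certificates ------------------

# colored graph for igraph: bond multiplicities become subdividing vertices
cg_colored <- function(g) {
  ne <- nrow(g$edges)
  n <- g$n
  col <- match(g$alpha, g$table$symbol)
  if (ne) {
    edges <- integer(0)
    for (k in seq_len(ne)) {
      mid <- n + k
      edges <- c(edges, g$edges[k, 1L], mid, mid, g$edges[k, 2L])
    }
    col <- c(col, nrow(g$table) + g$beta)
    h <- igraph::make_empty_graph(n = n + ne, directed = FALSE)
    h <- igraph::add_edges(h, edges)
  } else {
    h <- igraph::make_empty_graph(n = n, directed = FALSE)
  }
  list(graph = h, colors = col)
}

#' Are two chemical graphs isomorphic?
#'
#' Isomorphism must preserve element labels and bond multiplicities.
#'
#' @param g1,g2 \code{\link{chem_graph}} objects over the same element table.
#' @return logical.
#' @export
cg_isomorphic <- function(g1, g2) {
  if (g1$n != g2$n || nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  if (!identical(sort(g1$alpha), sort(g2$alpha))) return(FALSE)
  c1 <- cg_colored(g1); c2 <- cg_colored(g2)
  igraph::isomorphic(c1$graph, c2$graph, method = "vf2",
                     vertex.color1 = c1$colors, vertex.color2 = c2$colors)
}

#' Canonical certificate of a chemical graph
#'
#' A character string equal for two graphs exactly when they are isomorphic
#' as chemical graphs.  Used to deduplicate enumerated isomers and to fix a
#' deterministic output order.
#'
#' @param g a \code{\link{chem_graph}}.
#' @return character scalar.
#' @export
cg_certificate <- function(g) {
  cc <- cg_colored(g)
  perm <- igraph::canonical_permutation(cc$graph, colors = cc$colors)$labeling
  h <- igraph::permute(cc$graph, perm)
  el <- igraph::as_edgelist(h, names = FALSE)
  el <- t(apply(el, 1L, sort))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  colp <- integer(length(cc$colors)); colp[perm] <- cc$colors
  paste(length(cc$colors), paste(colp, collapse = ","),
        paste(el[, 1L], el[, 2L], sep = "-", collapse = ","), sep = ";")
}

#' Relabel the vertices of a chemical graph
#'
#' @param g a \code{\link{chem_graph}}.
#' @param perm permutation: new id of vertex \code{i} is \code{perm[i]}.
#' @return the relabeled \code{chem_graph} (isomorphic to \code{g}).
#' @export
cg_permute <- function(g, perm) {
  inv <- integer(g$n); inv[perm] <- seq_len(g$n)
  chem_graph(g$n, matrix(perm[g$edges], ncol = 2L), g$alpha[inv], g$beta, g$table)
}
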