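#' Element tables for hydrogen-suppressed chemical graphs
#'
#' An element table fixes, for every usable chemical element, a unique valence
#' in \code{[1,4]} and the integer mass surrogate \code{mass10 = floor(10 *
#' standard atomic mass)}.  A strict total order over the elements (ascending
#' lexicographic on the symbol) orients configuration tuples; it is stable
#' across serialization.
#'
#' @param symbols character vector of element symbols.
#' @param valence integer vector of valences, each in \code{[1,4]}.
#' @param mass numeric vector of standard atomic masses.
#' @return A data frame of class \code{"element_table"} with columns
#'   \code{symbol}, \code{valence}, \code{mass10} and \code{order_index},
#'   sorted by the element order.
#' @examples
#' element_table(c("C", "O"), c(4, 2), c(12.011, 15.999))
#' @export
element_table <- function(symbols, valence, mass) {
  stopifnot(length(symbols) == length(valence), length(symbols) == length(mass))
  if (anyDuplicated(symbols)) stop("duplicate element symbols")
  valence <- as.integer(valence)
  if (any(valence < 1L | valence > 4L)) stop("every valence must be in [1,4]")
  mass10 <- as.integer(floor(10 * mass))
  if (any(mass10 <= 0L)) stop("mass10 must be positive")
  ord <- order(symbols, method = "radix")
  tab <- data.frame(symbol = symbols[ord], valence = valence[ord],
                    mass10 = mass10[ord], stringsAsFactors = FALSE)
  tab$order_index <- seq_len(nrow(tab))
  class(tab) <- c("element_table", "data.frame")
  tab
}

#' Default element table
#'
#' Covers C, N, O, S, Cl with valences 4, 3, 2, 2, 1.  Compounds whose
#' elements use other valences (charged species, hexavalent sulfur, ...) are
#' outside the model and are skipped at load time.
#'
#' @return An \code{\link{element_table}}.
#' @export
default_element_table <- function() {
  element_table(c("C", "N", "O", "S", "Cl"),
                c(4L, 3L, 2L, 2L, 1L),
                c(12.011, 14.007, 15.999, 32.06, 35.45))
}

elem_valence <- function(table, a) {
  i <- match(a, table$symbol)
  if (anyNA(i)) stop("unknown element(s): ", paste(unique(a[is.na(i)]), collapse = ", "))
  table$valence[i]
}

elem_mass10 <- function(table, a) {
  i <- match(a, table$symbol)
  if (anyNA(i)) stop("unknown element(s): ", paste(unique(a[is.na(i)]), collapse = ", "))
  table$mass10[i]
}

#' Construct a validated hydrogen-suppressed chemical graph
#'
#' A chemical graph is a simple, connected, undirected graph whose vertices
#' carry element labels and whose edges carry bond multiplicities in
#' \code{[1,3]}, subject to the valence condition: at every vertex the sum of
#' incident bond multiplicities is at most the valence of its element.
#' Hydrogens are implicit; the hydro-degree \code{valence - bond sum} of a
#' vertex is its implicit hydrogen count.
#'
#' @param n number of vertices; vertices are the integers \code{1..n}.
#' @param edges two-column integer matrix of undirected edges (no loops, no
#'   parallel edges).
#' @param alpha character vector of length \code{n}: element symbol per vertex.
#' @param beta integer vector, one multiplicity in \code{[1,3]} per edge row.
#' @param table an \code{\link{element_table}}; defaults to
#'   \code{\link{default_element_table}()}.
#' @return An object of class \code{"chem_graph"}.
#' @examples
#' # ethane core: two carbons, one single bond
#' g <- chem_graph(2, rbind(c(1, 2)), c("C", "C"), 1)
#' hydro_degree(g, 1)  # 3 implicit hydrogens
#' @export
chem_graph <- function(n, edges, alpha, beta, table = default_element_table()) {
  n <- as.integer(n)
  if (n < 1L) stop("need at least one vertex")
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  beta <- as.integer(beta)
  if (length(beta) != nrow(edges)) stop("need one multiplicity per edge")
  if (length(alpha) != n) stop("need one element label per vertex")
  if (nrow(edges) > 0L) {
    if (any(edges < 1L | edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("loop edge not allowed")
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key)) stop("parallel edge not allowed")
    if (any(beta < 1L | beta > 3L)) stop("bond multiplicity must be in [1,3]")
    # canonical storage: smaller endpoint first
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, 2:1]
  }
  g <- structure(list(n = n, edges = edges, alpha = as.character(alpha),
                      beta = beta, table = table),
                 class = "chem_graph")
  if (!cg_connected(g)) stop("graph must be connected")
  bs <- cg_beta_sums(g)
  val <- elem_valence(table, g$alpha)
  bad <- which(bs > val)
  if (length(bad)) {
    stop(sprintf("valence violation at vertex %d: element %s has bond sum %d > valence %d",
                 bad[1L], g$alpha[bad[1L]], bs[bad[1L]], val[bad[1L]]))
  }
  g
}

#' @export
print.chem_graph <- function(x, ...) {
  cat(sprintf("chem_graph: %d vertices, %d edges, elements {%s}\n",
              x$n, nrow(x$edges), paste(sort(unique(x$alpha)), collapse = ",")))
  invisible(x)
}

# adjacency list: for each vertex, matrix with columns (neighbor, edge index)
cg_adjacency <- function(g) {
  adj <- vector("list", g$n)
  for (i in seq_len(g$n)) adj[[i]] <- cbind(integer(0), integer(0))
  if (nrow(g$edges)) {
    for (k in seq_len(nrow(g$edges))) {
      u <- g$edges[k, 1L]; v <- g$edges[k, 2L]
      adj[[u]] <- rbind(adj[[u]], c(v, k))
      adj[[v]] <- rbind(adj[[v]], c(u, k))
    }
  }
  adj
}

cg_degrees <- function(g) {
  d <- integer(g$n)
  if (nrow(g$edges)) {
    t1 <- tabulate(g$edges[, 1L], g$n)
    t2 <- tabulate(g$edges[, 2L], g$n)
    d <- t1 + t2
  }
  d
}

cg_beta_sums <- function(g) {
  bs <- integer(g$n)
  if (nrow(g$edges)) {
    for (k in seq_len(nrow(g$edges))) {
      bs[g$edges[k, 1L]] <- bs[g$edges[k, 1L]] + g$beta[k]
      bs[g$edges[k, 2L]] <- bs[g$edges[k, 2L]] + g$beta[k]
    }
  }
  bs
}

cg_connected <- function(g) {
  if (g$n == 1L) return(TRUE)
  seen <- logical(g$n)
  stack <- 1L; seen[1L] <- TRUE
  adj <- cg_adjacency(g)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    nb <- adj[[v]][, 1L]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  all(seen)
}

cg_to_igraph <- function(g) {
  h <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (nrow(g$edges)) h <- igraph::add_edges(h, as.integer(t(g$edges)))
  h
}

#' Sum of incident bond multiplicities
#'
#' @param g a \code{\link{chem_graph}}.
#' @param v vertex id (or vector of ids; default all vertices).
#' @return integer vector of bond-multiplicity sums.
#' @export
beta_sum <- function(g, v = seq_len(g$n)) {
  v <- as.integer(v)
  if (any(v < 1L | v > g$n)) stop("unknown vertex")
  cg_beta_sums(g)[v]
}

#' Implicit hydrogen count of a vertex
#'
#' \code{hydro_degree(g, v)} is the valence of the element at \code{v} minus
#' the sum of incident bond multiplicities.
#'
#' @inheritParams beta_sum
#' @return non-negative integer vector.
#' @export
hydro_degree <- function(g, v = seq_len(g$n)) {
  v <- as.integer(v)
  if (any(v < 1L | v > g$n)) stop("unknown vertex")
  elem_valence(g$table, g$alpha[v]) - beta_sum(g, v)
}

#' Cycle rank of a connected graph
#'
#' The minimum number of edges whose removal leaves the graph acyclic; for a
#' connected graph this is \code{|E| - |V| + 1}.
#'
#' @param g a \code{\link{chem_graph}}.
#' @return integer rank.
#' @export
graph_rank <- function(g) {
  nrow(g$edges) - g$n + 1L
}

#' Core edges and core vertices
#'
#' An edge is a core edge if it lies on a cycle, or is a bridge both of whose
#' sides contain a cycle.  Core vertices are the endpoints of core edges.
#' A tree has no core edges.
#'
#' @param g a \code{\link{chem_graph}}.
#' @return list with integer vectors \code{edges} (row indices into
#'   \code{g$edges}) and \code{vertices}.
#' @export
core_edges <- function(g) {
  m <- nrow(g$edges)
  if (m == 0L || graph_rank(g) == 0L) {
    return(list(edges = integer(0), vertices = integer(0)))
  }
  ig <- cg_to_igraph(g)
  br <- as.integer(igraph::bridges(ig))
  is_core <- rep(TRUE, m)
  is_core[br] <- FALSE
  # a bridge is core when both components after its removal contain a cycle
  for (k in br) {
    h <- igraph::delete_edges(ig, k)
    comp <- igraph::components(h)
    cyc <- logical(comp$no)
    el <- igraph::as_edgelist(h, names = FALSE)
    if (nrow(el)) {
      ec <- tabulate(comp$membership[el[, 1L]], comp$no)
      cyc <- ec >= comp$csize   # |E| >= |V| on a connected piece means a cycle
    }
    if (all(cyc[comp$membership[g$edges[k, ]]])) is_core[k] <- TRUE
  }
  ce <- which(is_core)
  list(edges = ce, vertices = sort(unique(as.integer(g$edges[ce, , drop = FALSE]))))
}

#' Bundle chemical graphs with observed property values
#'
#' @param graphs list of \code{\link{chem_graph}} objects.
#' @param values numeric property values, one per graph.
#' @param property_name name of the property.
#' @return An object of class \code{"chem_dataset"}.
#' @export
chem_dataset <- function(graphs, values, property_name = "property") {
  stopifnot(length(graphs) == length(values))
  if (!length(graphs)) stop("empty dataset")
  structure(list(graphs = graphs, values = as.numeric(values),
                 property_name = property_name),
            class = "chem_dataset")
}

#' @export
print.chem_dataset <- function(x, ...) {
  cat(sprintf("chem_dataset: %d graphs, property '%s' in [%.4g, %.4g]\n",
              length(x$graphs), x$property_name, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.chem_dataset <- function(x) length(x$graphs)
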