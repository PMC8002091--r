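#' Chemical symbol of a vertex
#'
#' The pair (element, degree) of a vertex in the hydrogen-suppressed graph,
#' written as e.g. \code{"C3"}.
#'
#' @param g a \code{\link{chem_graph}}.
#' @param v vertex ids (default all).
#' @return character vector of symbols.
#' @export
chemical_symbol <- function(g, v = seq_len(g$n)) {
  v <- as.integer(v)
  if (any(v < 1L | v > g$n)) stop("unknown vertex")
  d <- cg_degrees(g)[v]
  if (any(d > 4L)) stop("vertex degree exceeds 4: not a chemical graph vertex")
  paste0(g$alpha[v], d)
}

# split "C3" -> list(elem, deg)
split_symbol <- function(mu) {
  elem <- sub("[0-9]+$", "", mu)
  deg <- as.integer(sub("^[A-Za-z]+", "", mu))
  list(elem = elem, deg = deg)
}

# order key of a chemical symbol under (element order, degree)
symbol_rank <- function(mu, table) {
  s <- split_symbol(mu)
  match(s$elem, table$symbol) * 10L + s$deg
}

#' Adjacency-configuration of an edge
#'
#' The tuple (a, b, m) of endpoint elements and bond multiplicity, oriented so
#' that a <= b under the element order; returned as the string \code{"a,b,m"}.
#'
#' @param g a \code{\link{chem_graph}}.
#' @param e edge row indices (default all).
#' @return character vector.
#' @export
adjacency_config <- function(g, e = seq_len(nrow(g$edges))) {
  e <- as.integer(e)
  a <- g$alpha[g$edges[e, 1L]]
  b <- g$alpha[g$edges[e, 2L]]
  oa <- match(a, g$table$symbol); ob <- match(b, g$table$symbol)
  swap <- oa > ob
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste(a, b, g$beta[e], sep = ",")
}

#' Edge-configuration of an interior edge
#'
#' The tuple (mu, xi, m) of endpoint chemical symbols and bond multiplicity,
#' oriented mu <= xi under the order on symbols; returned as \code{"mu,xi,m"}.
#' Only defined on interior edges of the decomposition.
#'
#' @param g a \code{\link{chem_graph}}.
#' @param e edge row indices.
#' @param dec the \code{\link{two_layer}} decomposition of \code{g}.
#' @return character vector.
#' @export
edge_config <- function(g, e, dec) {
  e <- as.integer(e)
  if (!all(e %in% dec$interior_edges)) {
    stop("edge-configuration is only defined on interior edges")
  }
  cs <- chemical_symbol(g)
  mu <- cs[g$edges[e, 1L]]
  xi <- cs[g$edges[e, 2L]]
  ra <- symbol_rank(mu, g$table); rb <- symbol_rank(xi, g$table)
  swap <- ra > rb
  tmp <- mu[swap]; mu[swap] <- xi[swap]; xi[swap] <- tmp
  paste(mu, xi, g$beta[e], sep = ",")
}

# drop degrees from an edge-configuration string: "C2,O1,2" stays, "a,b,m"
ec_to_ac <- function(gamma, table) {
  parts <- strsplit(gamma, ",", fixed = TRUE)
  vapply(parts, function(p) {
    a <- sub("[0-9]+$", "", p[1L]); b <- sub("[0-9]+$", "", p[2L])
    if (match(a, table$symbol) > match(b, table$symbol)) { t <- a; a <- b; b <- t }
    paste(a, b, p[3L], sep = ",")
  }, character(1))
}

#' All possible edge-configurations over an element set
#'
#' Every tuple (ad, bd', m) of chemical symbols over \code{elements} with
#' degrees in \code{[1,4]} and multiplicity in \code{[1,3]}, in canonical
#' orientation, subject to the valence of each endpoint admitting its degree
#' and multiplicity.  Useful for specifications that allow every
#' configuration.
#'
#' @param elements element symbols.
#' @param table an \code{\link{element_table}}.
#' @return character vector of configuration strings \code{"ad,bd,m"}.
#' @export
all_edge_configs <- function(elements, table = default_element_table()) {
  syms <- character(0)
  for (a in elements) {
    for (d in seq_len(min(4L, elem_valence(table, a)))) syms <- c(syms, paste0(a, d))
  }
  out <- character(0)
  for (i in seq_along(syms)) for (j in i:length(syms)) for (m in 1:3) {
    si <- split_symbol(syms[i]); sj <- split_symbol(syms[j])
    # the bond with multiplicity m must fit into both endpoints' valences
    if (elem_valence(table, si$elem) - (si$deg - 1L) < m) next
    if (elem_valence(table, sj$elem) - (sj$deg - 1L) < m) next
    out <- c(out, paste(syms[i], syms[j], m, sep = ","))
  }
  out
}

#' Build the descriptor space of a dataset
#'
#' Collects, over every graph in the dataset decomposed at branch-parameter
#' \code{rho}: the elements on interior vertices, the elements on exterior
#' vertices, the edge-configurations of interior edges, and the canonical
#' codes of all rho-fringe-trees.  Each set receives a deterministic integer
#' encoding (elements in element-table order, edge-configurations by symbol
#' order, codes lexicographically).  The feature-vector length is
#' \code{K = 17 + |lambda_int| + |lambda_ex| + |gamma_int| + |fringe_set|}.
#'
#' @param dataset a \code{\link{chem_dataset}} (or plain list of graphs).
#' @param rho branch-parameter.
#' @return An object of class \code{"descriptor_space"}.
#' @export
build_descriptor_space <- function(dataset, rho) {
  graphs <- if (inherits(dataset, "chem_dataset")) dataset$graphs else dataset
  if (!length(graphs)) stop("empty dataset")
  table <- graphs[[1L]]$table
  lam_int <- character(0); lam_ex <- character(0)
  gam <- character(0); fcodes <- character(0)
  for (g in graphs) {
    dec <- two_layer(g, rho)
    lam_int <- union(lam_int, unique(g$alpha[dec$interior_vertices]))
    lam_ex <- union(lam_ex, unique(g$alpha[dec$exterior_vertices]))
    if (length(dec$interior_edges)) {
      gam <- union(gam, unique(edge_config(g, dec$interior_edges, dec)))
    }
    fcodes <- union(fcodes, unique(vapply(dec$fringe_trees, canonical_code, character(1))))
  }
  descriptor_space(lam_int, lam_ex, gam, fcodes, rho, table)
}

#' Assemble a descriptor space from explicit encodings
#'
#' @param lambda_int,lambda_ex element symbols on interior / exterior vertices.
#' @param gamma_int interior edge-configuration strings \code{"mu,xi,m"}.
#' @param fringe_codes canonical fringe-tree codes.
#' @param rho branch-parameter.
#' @param table an \code{\link{element_table}}.
#' @return An object of class \code{"descriptor_space"}.
#' @export
descriptor_space <- function(lambda_int, lambda_ex, gamma_int, fringe_codes,
                             rho, table = default_element_table()) {
  lam_int <- table$symbol[sort(match(unique(lambda_int), table$symbol))]
  lam_ex <- table$symbol[sort(match(unique(lambda_ex), table$symbol))]
  gam <- unique(gamma_int)
  gkey <- vapply(strsplit(gam, ",", fixed = TRUE), function(p) {
    sprintf("%03d%03d%s", symbol_rank(p[1L], table), symbol_rank(p[2L], table), p[3L])
  }, character(1))
  gam <- gam[order(gkey, method = "radix")]
  fcodes <- sort(unique(fringe_codes), method = "radix")
  K <- 17L + length(lam_int) + length(lam_ex) + length(gam) + length(fcodes)
  slots <- c("n", "n_int", "ms_avg",
             paste0("dg_", 1:4), paste0("dg_int_", 1:4),
             paste0("hydg_", 0:3), paste0("bd_int_", 2:3),
             if (length(lam_int)) paste0("na_int_", lam_int),
             if (length(lam_ex)) paste0("na_ex_", lam_ex),
             if (length(gam)) paste0("ec_(", gam, ")"),
             if (length(fcodes)) paste0("fc_", fcodes))
  structure(list(lambda_int = lam_int, lambda_ex = lam_ex,
                 gamma_int = gam, fringe_set = fcodes,
                 rho = as.integer(rho), K = K, table = table,
                 slot_names = slots),
            class = "descriptor_space")
}

#' @export
print.descriptor_space <- function(x, ...) {
  cat(sprintf(paste0("descriptor_space (rho = %d): K = %d",
                     " (17 + %d interior elements + %d exterior elements",
                     " + %d edge-configurations + %d fringe codes)\n"),
              x$rho, x$K, length(x$lambda_int), length(x$lambda_ex),
              length(x$gamma_int), length(x$fringe_set)))
  invisible(x)
}

#' Feature vector of a chemical graph
#'
#' The K descriptors, in fixed slot order: vertex count n; interior vertex
#' count; average mass surrogate; interior vertices by degree in G (1..4);
#' interior vertices by degree within the interior subgraph (1..4); vertices
#' by hydro-degree (0..3); interior edges of bond multiplicity 2 and 3;
#' interior and exterior element frequencies; interior edge-configuration
#' frequencies; fringe-tree code frequencies.
#'
#' @param g a \code{\link{chem_graph}}.
#' @param space a \code{\link{descriptor_space}}.
#' @param dec optional precomputed \code{\link{two_layer}} decomposition.
#' @return named numeric vector of length \code{space$K}.  If the graph uses
#'   an element, configuration or fringe code absent from the space, an error
#'   of class \code{"moldesign_out_of_space"} is signalled listing the missing
#'   codes.
#' @export
feature_vector <- function(g, space, dec = NULL) {
  if (is.null(dec)) dec <- two_layer(g, space$rho)
  int <- dec$interior_vertices
  ext <- dec$exterior_vertices
  ecs <- if (length(dec$interior_edges)) edge_config(g, dec$interior_edges, dec) else character(0)
  codes <- vapply(dec$fringe_trees, canonical_code, character(1))
  missing <- c(setdiff(unique(g$alpha[int]), space$lambda_int),
               setdiff(unique(g$alpha[ext]), space$lambda_ex),
               setdiff(unique(ecs), space$gamma_int),
               setdiff(unique(codes), space$fringe_set))
  if (length(missing)) {
    stop(structure(class = c("moldesign_out_of_space", "error", "condition"),
                   list(message = paste("graph uses codes absent from the descriptor space:",
                                        paste(missing, collapse = "; ")),
                        call = sys.call(-1), missing = missing)))
  }
  deg <- cg_degrees(g)
  x <- numeric(space$K)
  names(x) <- space$slot_names
  x["n"] <- g$n
  x["n_int"] <- length(int)
  x["ms_avg"] <- sum(elem_mass10(g$table, g$alpha)) / g$n
  for (d in 1:4) x[paste0("dg_", d)] <- sum(deg[int] == d)
  # degrees within the interior subgraph
  ideg <- integer(g$n)
  for (k in dec$interior_edges) {
    ideg[g$edges[k, 1L]] <- ideg[g$edges[k, 1L]] + 1L
    ideg[g$edges[k, 2L]] <- ideg[g$edges[k, 2L]] + 1L
  }
  for (d in 1:4) x[paste0("dg_int_", d)] <- sum(ideg[int] == d)
  hyd <- hydro_degree(g)
  for (d in 0:3) x[paste0("hydg_", d)] <- sum(hyd == d)
  for (m in 2:3) x[paste0("bd_int_", m)] <- sum(g$beta[dec$interior_edges] == m)
  for (a in space$lambda_int) x[paste0("na_int_", a)] <- sum(g$alpha[int] == a)
  for (a in space$lambda_ex) x[paste0("na_ex_", a)] <- sum(g$alpha[ext] == a)
  if (length(ecs)) {
    tb <- table(ecs)
    x[paste0("ec_(", names(tb), ")")] <- as.integer(tb)
  }
  tb <- table(codes)
  x[paste0("fc_", names(tb))] <- as.integer(tb)
  x
}

#' Feature matrix of a dataset
#'
#' @param dataset a \code{\link{chem_dataset}} or list of graphs.
#' @param space a \code{\link{descriptor_space}}.
#' @return numeric matrix, one row per graph, columns named by slot.
#' @export
feature_matrix <- function(dataset, space) {
  graphs <- if (inherits(dataset, "chem_dataset")) dataset$graphs else dataset
  t(vapply(graphs, feature_vector, numeric(space$K), space = space))
}

#' Write a feature matrix as CSV
#'
#' @param x matrix from \code{\link{feature_matrix}}.
#' @param path output file.
#' @export
write_feature_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x, check.names = FALSE), path, row.names = FALSE)
}
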