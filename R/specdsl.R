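#' Seed graph of a target specification
#'
#' An abstract multigraph whose edges carry expansion classes: \code{"ge2"}
#' edges are replaced by a path of length at least 2, \code{"ge1"} by a path
#' of length at least 1, \code{"e01"} edges are kept or dropped, and
#' \code{"eq1"} edges are kept as they are.  Parallel edges are allowed
#' (edges are keyed by index, not endpoint pair); edge \code{i} is named
#' \code{a<i>} for use in side constraints.
#'
#' @param n number of seed vertices (ids \code{1..n}).
#' @param edges two-column matrix of endpoints.
#' @param classes character vector, one class per edge.
#' @return object of class \code{"seed_graph"}.
#' @export
seed_graph <- function(n, edges, classes) {
  n <- as.integer(n)
  edges <- matrix(as.integer(edges), ncol = 2L)
  classes <- as.character(classes)
  if (nrow(edges) != length(classes)) stop("one class per edge required")
  if (!all(classes %in% c("ge2", "ge1", "e01", "eq1"))) {
    stop("edge classes must be ge2, ge1, e01 or eq1")
  }
  if (nrow(edges) && any(edges < 1L | edges > n)) stop("seed edge endpoint out of range")
  if (nrow(edges) && any(edges[, 1L] == edges[, 2L])) stop("seed self-loops not supported")
  structure(list(n = n, edges = edges, classes = classes,
                 edge_names = if (nrow(edges)) paste0("a", seq_len(nrow(edges))) else character(0)),
            class = "seed_graph")
}

#' @export
print.seed_graph <- function(x, ...) {
  cat(sprintf("seed_graph: %d vertices, %d edges (%s)\n", x$n, nrow(x$edges),
              paste(sprintf("%s:%s-%s:%s", x$edge_names, x$edges[, 1L],
                            x$edges[, 2L], x$classes), collapse = ", ")))
  invisible(x)
}

# default per-edge length bounds by class
class_l_bounds <- function(classes, n_star) {
  lb <- ifelse(classes == "ge2", 2L, ifelse(classes == "ge1", 1L,
        ifelse(classes == "e01", 0L, 1L)))
  ub <- ifelse(classes == "ge2", n_star, ifelse(classes == "ge1", n_star,
        ifelse(classes == "e01", 1L, 1L)))
  list(lb = as.integer(lb), ub = as.integer(pmax(lb, ub)))
}

fill_bound <- function(x, default, len, what) {
  if (is.null(x)) return(rep(as.integer(default), len))
  if (length(x) == 1L) return(rep(as.integer(x), len))
  if (length(x) != len) stop("bound '", what, "' has wrong length")
  as.integer(x)
}

fill_named <- function(x, keys, default) {
  out <- stats::setNames(rep(as.numeric(default), length(keys)), keys)
  if (!is.null(x)) {
    unknown <- setdiff(names(x), keys)
    if (length(unknown)) stop("bounds given for unknown keys: ", paste(unknown, collapse = ", "))
    out[names(x)] <- as.numeric(x)
  }
  out
}

#' Assemble and validate a target specification
#'
#' Bundles a seed graph, interior specification (size and path-length bounds)
#' and chemical specification (element, fringe-tree and configuration bounds)
#' into one validated object.  Unspecified lower bounds default to 0 and
#' unspecified upper bounds to \code{n_star}.
#'
#' @param seed a \code{\link{seed_graph}}.
#' @param rho branch-parameter of the target decomposition.
#' @param n_star upper bound on the number of (non-hydrogen) vertices.
#' @param n_lb lower bound on the number of vertices.
#' @param n_int_lb,n_int_ub bounds on the number of interior vertices.
#' @param interior optional list of per-edge/per-vertex interior bounds:
#'   \code{l_lb,l_ub} (path lengths), \code{bl_lb,bl_ub} (leaf paths attached
#'   to internal path vertices), \code{ch_lb,ch_ub} (max leaf-path length on a
#'   path), \code{v_bl_lb,v_bl_ub} (leaf-path indicator per seed vertex, in
#'   \{0,1\}), \code{v_ch_lb,v_ch_ub} (leaf-path length per seed vertex),
#'   \code{bd2_lb,bd2_ub,bd3_lb,bd3_ub} (multi-bond counts per seed edge path).
#' @param chem optional list: \code{lambda_int} (allowed interior elements),
#'   \code{lambda_star} (list of allowed element sets per seed vertex),
#'   \code{lambda_dg_int} (allowed chemical symbols), \code{gamma_int}
#'   (allowed interior edge-configurations), \code{fringe_v} (list of
#'   candidate fringe-code sets per seed vertex), \code{fringe_e} (candidate
#'   codes for non-seed interior vertices), and named bound vectors
#'   \code{na_lb,na_ub,na_int_lb,na_int_ub,ns_int_lb,ns_int_ub,
#'   ac_int_lb,ac_int_ub,ec_int_lb,ec_int_ub}.
#' @param side list of linear side constraints over seed-edge path lengths,
#'   each \code{list(coef = c(a1 = 1, a2 = -1), op = "<=", rhs = 0)}.
#' @param table an \code{\link{element_table}}.
#' @return object of class \code{"target_spec"}.
#' @export
target_spec <- function(seed, rho, n_star, n_lb = 0L,
                        n_int_lb = 0L, n_int_ub = n_star,
                        interior = list(), chem = list(), side = list(),
                        table = default_element_table()) {
  stopifnot(inherits(seed, "seed_graph"))
  m <- nrow(seed$edges); p <- seed$n
  n_star <- as.integer(n_star)
  errs <- character(0)
  cl <- class_l_bounds(seed$classes, n_star)
  int <- list(
    n_int_lb = as.integer(n_int_lb), n_int_ub = as.integer(n_int_ub),
    l_lb = pmax(fill_bound(interior$l_lb, 0L, m, "l_lb"), cl$lb),
    l_ub = pmin(fill_bound(interior$l_ub, n_star, m, "l_ub"), cl$ub),
    bl_lb = fill_bound(interior$bl_lb, 0L, m, "bl_lb"),
    bl_ub = fill_bound(interior$bl_ub, n_star, m, "bl_ub"),
    ch_lb = fill_bound(interior$ch_lb, 0L, m, "ch_lb"),
    ch_ub = fill_bound(interior$ch_ub, n_star, m, "ch_ub"),
    v_bl_lb = fill_bound(interior$v_bl_lb, 0L, p, "v_bl_lb"),
    v_bl_ub = pmin(fill_bound(interior$v_bl_ub, 1L, p, "v_bl_ub"), 1L),
    v_ch_lb = fill_bound(interior$v_ch_lb, 0L, p, "v_ch_lb"),
    v_ch_ub = fill_bound(interior$v_ch_ub, n_star, p, "v_ch_ub"),
    bd2_lb = fill_bound(interior$bd2_lb, 0L, m, "bd2_lb"),
    bd2_ub = fill_bound(interior$bd2_ub, n_star, m, "bd2_ub"),
    bd3_lb = fill_bound(interior$bd3_lb, 0L, m, "bd3_lb"),
    bd3_ub = fill_bound(interior$bd3_ub, n_star, m, "bd3_ub"))
  # subdivision classes force parts of the length bounds
  if (any(int$l_lb > int$l_ub)) errs <- c(errs, "l_lb exceeds l_ub on some edge")
  if (int$n_int_lb > int$n_int_ub) errs <- c(errs, "n_int_lb > n_int_ub")

  lambda_int <- chem$lambda_int
  if (is.null(lambda_int)) stop("chem$lambda_int is required")
  if (!all(lambda_int %in% table$symbol)) errs <- c(errs, "unknown element in lambda_int")
  lambda_star <- chem$lambda_star
  if (is.null(lambda_star)) {
    lambda_star <- rep(list(lambda_int[elem_valence(table, lambda_int) >= 2L]), p)
  }
  if (length(lambda_star) != p) stop("lambda_star must have one element set per seed vertex")
  for (v in seq_len(p)) {
    ls <- lambda_star[[v]]
    if (any(elem_valence(table, ls) < 2L)) {
      errs <- c(errs, sprintf("lambda_star[[%d]] contains an element of valence < 2", v))
    }
  }
  all_symbols <- as.vector(outer(lambda_int, 1:4, paste0))
  lambda_dg_int <- chem$lambda_dg_int
  if (is.null(lambda_dg_int)) lambda_dg_int <- all_symbols
  gamma_int <- chem$gamma_int
  if (is.null(gamma_int)) stop("chem$gamma_int (allowed edge-configurations) is required")
  fringe_e <- chem$fringe_e
  if (is.null(fringe_e)) stop("chem$fringe_e (candidate fringe codes) is required")
  fringe_v <- chem$fringe_v
  if (is.null(fringe_v)) fringe_v <- rep(list(fringe_e), p)
  if (length(fringe_v) != p) stop("fringe_v must have one candidate set per seed vertex")
  f_star <- unique(c(fringe_e, unlist(fringe_v)))
  for (code in f_star) {
    t <- parse_fringe_code(code)
    if (t$height > rho) errs <- c(errs, sprintf("fringe tree %s taller than rho", code))
  }
  ac_keys <- unique(ec_to_ac(gamma_int, table))
  ce <- list(
    n_lb = as.integer(n_lb), n_star = n_star,
    lambda_int = lambda_int, lambda_star = lambda_star,
    lambda_dg_int = lambda_dg_int, gamma_int = gamma_int,
    fringe_v = fringe_v, fringe_e = fringe_e, f_star = f_star,
    na_lb = fill_named(chem$na_lb, union(lambda_int, fringe_elements(f_star)), 0),
    na_ub = fill_named(chem$na_ub, union(lambda_int, fringe_elements(f_star)), n_star),
    na_int_lb = fill_named(chem$na_int_lb, lambda_int, 0),
    na_int_ub = fill_named(chem$na_int_ub, lambda_int, n_star),
    ns_int_lb = fill_named(chem$ns_int_lb, lambda_dg_int, 0),
    ns_int_ub = fill_named(chem$ns_int_ub, lambda_dg_int, n_star),
    ac_int_lb = fill_named(chem$ac_int_lb, ac_keys, 0),
    ac_int_ub = fill_named(chem$ac_int_ub, ac_keys, n_star),
    ec_int_lb = fill_named(chem$ec_int_lb, gamma_int, 0),
    ec_int_ub = fill_named(chem$ec_int_ub, gamma_int, n_star))
  if (!(int$n_int_lb <= ce$n_lb && ce$n_lb <= ce$n_star)) {
    # the size chain n_int_lb <= n_lb <= n_star must hold
    errs <- c(errs, "size bounds must satisfy n_int_lb <= n_lb <= n_star")
  }
  for (b in c("bl", "ch", "bd2", "bd3")) {
    if (any(int[[paste0(b, "_lb")]] > int[[paste0(b, "_ub")]])) {
      errs <- c(errs, sprintf("%s_lb exceeds %s_ub on some edge", b, b))
    }
  }
  for (s in side) {
    if (!all(names(s$coef) %in% seed$edge_names)) {
      errs <- c(errs, "side constraint references unknown seed edge")
    }
  }
  if (length(errs)) {
    stop(structure(class = c("moldesign_spec_error", "error", "condition"),
                   list(message = paste("invalid specification:",
                                        paste(errs, collapse = "; ")),
                        call = sys.call(-1), errors = errs)))
  }
  structure(list(seed = seed, rho = as.integer(rho), interior = int,
                 chem = ce, side = side, table = table),
            class = "target_spec")
}

fringe_elements <- function(codes) {
  unique(unlist(lapply(codes, function(cd) parse_fringe_code(cd)$alpha)))
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf(paste0("target_spec: seed %d vertices / %d edges (%s), rho = %d,\n",
                     "  n in [%d, %d], n_int in [%d, %d], |F*| = %d, |Gamma_int| = %d\n"),
              x$seed$n, nrow(x$seed$edges),
              paste(table(factor(x$seed$classes, c("ge2","ge1","e01","eq1"))), collapse = "/"),
              x$rho, x$chem$n_lb, x$chem$n_star,
              x$interior$n_int_lb, x$interior$n_int_ub,
              length(x$chem$f_star), length(x$chem$gamma_int)))
  invisible(x)
}

#' Write a target specification to a JSON file
#'
#' @param spec a \code{\link{target_spec}}.
#' @param path output path.
#' @export
write_target_spec <- function(spec, path) {
  obj <- list(
    seed_graph = list(n = spec$seed$n,
                      edges = spec$seed$edges,
                      classes = spec$seed$classes),
    rho = spec$rho,
    interior_spec = spec$interior,
    chemical_spec = spec$chem[setdiff(names(spec$chem), "f_star")],
    side_constraints = lapply(spec$side, function(s) {
      list(coef = as.list(s$coef), op = s$op, rhs = s$rhs)
    }),
    elements = list(symbol = spec$table$symbol, valence = spec$table$valence,
                    mass10 = spec$table$mass10))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a target specification from a JSON file
#'
#' @param path JSON file written by \code{\link{write_target_spec}} (or by
#'   hand, same schema).
#' @return a validated \code{\link{target_spec}}.
#' @export
read_target_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- element_table(obj$elements$symbol, obj$elements$valence,
                       obj$elements$mass10 / 10 + 0.001)
  tab$mass10 <- as.integer(obj$elements$mass10)
  sg <- seed_graph(obj$seed_graph$n, obj$seed_graph$edges, obj$seed_graph$classes)
  it <- obj$interior_spec
  ch <- obj$chemical_spec
  # jsonlite reads lists of sets back as lists of character vectors
  listify <- function(x, p) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) as.character(x[i, ])))
    out <- lapply(seq_len(p), function(i) as.character(unlist(x[[i]])))
    out
  }
  ch$lambda_star <- listify(ch$lambda_star, sg$n)
  ch$fringe_v <- listify(ch$fringe_v, sg$n)
  named <- function(x) if (is.null(x)) NULL else unlist(x)
  for (nm in c("na_lb","na_ub","na_int_lb","na_int_ub","ns_int_lb","ns_int_ub",
               "ac_int_lb","ac_int_ub","ec_int_lb","ec_int_ub")) {
    ch[[nm]] <- named(ch[[nm]])
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  side <- lapply(raw$side_constraints, function(s) {
    list(coef = unlist(s$coef), op = s$op, rhs = s$rhs)
  })
  target_spec(sg, obj$rho, n_star = ch$n_star, n_lb = ch$n_lb,
              n_int_lb = it$n_int_lb, n_int_ub = it$n_int_ub,
              interior = it[setdiff(names(it), c("n_int_lb", "n_int_ub"))],
              chem = ch[setdiff(names(ch), c("n_lb", "n_star"))],
              side = side, table = tab)
}
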