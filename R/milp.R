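# Minimal mixed-integer linear programming container and solver bridge.
#
# Instances are built in R (variables, bounds, integrality, sparse
# constraints), serialized to JSON and solved by the HiGHS branch-and-bound
# behind scipy.optimize.milp through the `python` interpreter on the PATH.
# Several instances can be solved in one interpreter call, which amortizes
# startup cost across e.g. the forward-equivalence probes.

milp_new <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$name <- character(0)
  env$lb <- numeric(0); env$ub <- numeric(0)
  env$integer <- logical(0)
  env$obj <- numeric(0)
  env$con_i <- list()   # per constraint: variable indices
  env$con_x <- list()   # per constraint: coefficients
  env$con_lb <- numeric(0); env$con_ub <- numeric(0)
  class(env) <- "milp_problem"
  env
}

milp_add_var <- function(m, name, lb, ub, integer = FALSE, obj = 0) {
  m$n <- m$n + 1L
  m$name[m$n] <- name
  m$lb[m$n] <- lb; m$ub[m$n] <- ub
  m$integer[m$n] <- integer
  m$obj[m$n] <- obj
  m$n
}

milp_add_vars <- function(m, names, lb, ub, integer = FALSE) {
  vapply(seq_along(names), function(i) {
    milp_add_var(m, names[i],
                 if (length(lb) > 1L) lb[i] else lb,
                 if (length(ub) > 1L) ub[i] else ub, integer)
  }, integer(1))
}

# lhs given as expr list(idx=, coef=, const=) or as (idx, coef)
milp_add_con <- function(m, idx, coef, lb = -Inf, ub = Inf) {
  keep <- coef != 0
  idx <- idx[keep]; coef <- coef[keep]
  if (length(idx) == 0L) {
    if (lb > 0 || ub < 0) {
      # constant constraint that cannot hold: encode explicit infeasibility
      v <- milp_add_var(m, ".infeasible", 0, 0)
      k <- length(m$con_lb) + 1L
      m$con_i[[k]] <- v; m$con_x[[k]] <- 1
      m$con_lb[k] <- 1; m$con_ub[k] <- Inf
    }
    return(invisible(NULL))
  }
  # merge duplicate indices
  agg <- rowsum(coef, idx)
  k <- length(m$con_lb) + 1L
  m$con_i[[k]] <- as.integer(rownames(agg))
  m$con_x[[k]] <- as.numeric(agg)
  m$con_lb[k] <- lb; m$con_ub[k] <- ub
  invisible(NULL)
}

# linear expressions: list(idx, coef, const)
expr_new <- function(idx = integer(0), coef = numeric(0), const = 0) {
  list(idx = as.integer(idx), coef = as.numeric(coef), const = const)
}

expr_add <- function(...) {
  es <- list(...)
  expr_new(unlist(lapply(es, `[[`, "idx")),
           unlist(lapply(es, `[[`, "coef")),
           sum(vapply(es, `[[`, numeric(1), "const")))
}

expr_scale <- function(e, s) expr_new(e$idx, e$coef * s, e$const * s)

# add constraint lb <= expr <= ub
milp_con_expr <- function(m, e, lb = -Inf, ub = Inf) {
  milp_add_con(m, e$idx, e$coef, lb - e$const, ub - e$const)
}

# evaluate an expression on a solution vector
expr_eval <- function(e, x) {
  if (length(e$idx)) sum(e$coef * x[e$idx]) + e$const else e$const
}

milp_counts <- function(m) c(variables = m$n, constraints = length(m$con_lb))

#' @keywords internal
milp_to_list <- function(m) {
  ti <- unlist(m$con_i); tx <- unlist(m$con_x)
  tr <- unlist(lapply(seq_along(m$con_i), function(k) rep(k, length(m$con_i[[k]]))))
  if (is.null(ti)) { ti <- integer(0); tx <- numeric(0); tr <- integer(0) }
  list(n = m$n, obj = I(m$obj), lb = I(m$lb), ub = I(m$ub),
       integrality = I(as.integer(m$integer)),
       a_row = I(as.integer(tr - 1L)), a_col = I(as.integer(ti - 1L)), a_val = I(tx),
       con_lb = I(m$con_lb), con_ub = I(m$con_ub))
}

python_bin <- function() {
  p <- Sys.getenv("MOLDESIGN_PYTHON", "")
  if (nzchar(p)) return(p)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no python interpreter found on the PATH")
  p
}

#' Solve one or more MILP instances
#'
#' @param problems a single \code{milp_problem} or list of them.
#' @param time_limit per-instance time limit in seconds.
#' @return for each instance, a list with \code{status} (\code{"optimal"},
#'   \code{"infeasible"}, \code{"limit"}, \code{"unbounded"} or
#'   \code{"error"}), the solution vector \code{x} and objective \code{fun}.
#' @keywords internal
solve_milp <- function(problems, time_limit = 120, objective_target = NULL,
                       heuristic_effort = NULL) {
  single <- inherits(problems, "milp_problem")
  if (single) problems <- list(problems)
  payload <- list(time_limit = time_limit,
                  problems = lapply(problems, milp_to_list))
  if (!is.null(objective_target)) payload$objective_target <- objective_target
  if (!is.null(heuristic_effort)) payload$heuristic_effort <- heuristic_effort
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "milp_solve.py", package = "moldesign")
  if (script == "") {
    # during development (load_all) fall back to the source tree
    script <- file.path("inst", "python", "milp_solve.py")
  }
  rc <- system2(python_bin(), c(shQuote(script), shQuote(fin), shQuote(fout)),
                stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("MILP solver failed: ", paste(rc, collapse = "\n"))
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  out <- lapply(seq_along(problems), function(k) {
    r <- if (is.data.frame(res)) as.list(res[k, , drop = FALSE]) else res[[k]]
    x <- r$x
    if (is.list(x)) x <- x[[1L]]
    list(status = as.character(r$status),
         x = if (!is.null(x) && length(x)) as.numeric(unlist(x)) else NULL,
         fun = if (!is.null(r$fun)) as.numeric(r$fun)[1L] else NULL)
  })
  if (single) out[[1L]] else out
}
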