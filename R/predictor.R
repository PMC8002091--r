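#' Fit a ReLU feed-forward regressor on feature vectors
#'
#' A fully connected network with one or two hidden layers of rectified-linear
#' units and a single linear output, trained with Adam on the mean squared
#' error.  Inputs are min-max scaled internally for conditioning; the scaling
#' is folded back into the first layer's weights before the model is returned,
#' so the stored network operates on raw descriptor values.  That keeps the
#' network affine-in-the-inputs per ReLU region and lets the inversion step
#' consume integer descriptors directly.
#'
#' @param x numeric feature matrix (rows = graphs) or a
#'   \code{\link{chem_dataset}} together with \code{space}.
#' @param y numeric response (ignored when \code{x} is a dataset).
#' @param hidden integer vector of hidden-layer widths (length 1 or 2).
#' @param space a \code{\link{descriptor_space}} when \code{x} is a dataset.
#' @param seed integer seed controlling initialization and minibatching.
#' @param epochs training epochs.
#' @param lr Adam step size.
#' @param verbose print loss every 200 epochs.
#' @return object of class \code{"mlp_net"}: \code{weights} (list of
#'   matrices, input side first), \code{biases}, \code{architecture}
#'   (\code{c(K, hidden, 1)}), fitted values and training R-squared.
#' @export
mlp_fit <- function(x, y = NULL, hidden = c(16L), space = NULL, seed = 1L,
                    epochs = 3000L, lr = 0.01, verbose = FALSE) {
  if (inherits(x, "chem_dataset")) {
    if (is.null(space)) stop("a descriptor space is required to featurize a dataset")
    y <- x$values
    x <- feature_matrix(x, space)
  }
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), length(hidden) %in% 1:2)
  K <- ncol(x)
  set.seed(seed)
  mn <- apply(x, 2L, min); mx <- apply(x, 2L, max)
  rg <- ifelse(mx > mn, mx - mn, 1)
  xs <- sweep(sweep(x, 2L, mn), 2L, rg, "/")
  sizes <- c(K, as.integer(hidden), 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(z) z * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(xs)
  for (ep in seq_len(epochs)) {
    # forward
    a <- vector("list", L + 1L); a[[1L]] <- xs
    z <- vector("list", L)
    for (l in seq_len(L)) {
      z[[l]] <- sweep(a[[l]] %*% W[[l]], 2L, b[[l]], "+")
      a[[l + 1L]] <- if (l < L) pmax(z[[l]], 0) else z[[l]]
    }
    err <- a[[L + 1L]][, 1L] - y
    if (verbose && ep %% 200L == 0L) {
      cat(sprintf("epoch %d  mse %.6g\n", ep, mean(err^2)))
    }
    # backward
    delta <- matrix(2 * err / n, n, 1L)
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in rev(seq_len(L))) {
      gW[[l]] <- crossprod(a[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1L) delta <- (delta %*% t(W[[l]])) * (z[[l - 1L]] > 0)
    }
    t_ <- ep
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - beta1^t_)) / (sqrt(vW[[l]] / (1 - beta2^t_)) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - beta1^t_)) / (sqrt(vb[[l]] / (1 - beta2^t_)) + eps)
    }
  }
  # fold the min-max scaling into the first layer
  W1 <- W[[1L]] / rg
  b[[1L]] <- b[[1L]] - as.numeric(crossprod(W[[1L]], mn / rg))
  W[[1L]] <- W1
  net <- structure(list(weights = W, biases = b,
                        architecture = sizes,
                        slot_names = colnames(x),
                        train_seed = seed),
                   class = "mlp_net")
  fit <- predict(net, x)
  net$fitted <- fit
  net$y <- y
  net$r2_train <- if (stats::var(y) > 0) 1 - sum((y - fit)^2) / sum((y - mean(y))^2) else NA_real_
  net
}

#' @export
predict.mlp_net <- function(object, newdata, ...) {
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (ncol(x) != object$architecture[1L]) {
    stop(sprintf("input has %d columns; network expects %d", ncol(x), object$architecture[1L]))
  }
  L <- length(object$weights)
  a <- x
  for (l in seq_len(L)) {
    z <- sweep(a %*% object$weights[[l]], 2L, object$biases[[l]], "+")
    a <- if (l < L) pmax(z, 0) else z
  }
  as.numeric(a[, 1L])
}

#' @export
print.mlp_net <- function(x, ...) {
  cat(sprintf("mlp_net: architecture (%s), training R^2 %s\n",
              paste(x$architecture, collapse = ","),
              if (is.null(x$r2_train) || is.na(x$r2_train)) "undefined" else sprintf("%.4f", x$r2_train)))
  invisible(x)
}

#' @export
summary.mlp_net <- function(object, ...) {
  print(object)
  np <- sum(vapply(object$weights, length, numeric(1))) +
    sum(vapply(object$biases, length, numeric(1)))
  cat(sprintf("  %d trainable parameters, %d training examples\n",
              np, length(object$y)))
  invisible(object)
}

#' @export
coef.mlp_net <- function(object, ...) {
  list(weights = object$weights, biases = object$biases)
}

#' @export
residuals.mlp_net <- function(object, ...) object$y - object$fitted

#' Coefficient of determination of a predictor on a dataset
#'
#' Computed exactly as \code{1 - sum((a - eta)^2) / sum((a - mean(a))^2)}
#' over the supplied observations.
#'
#' @param net an \code{"mlp_net"} (or any object usable with
#'   \code{predict(net, x)}).
#' @param x feature matrix or \code{\link{chem_dataset}}.
#' @param y observed values (taken from the dataset if omitted).
#' @param space required when \code{x} is a dataset.
#' @return numeric scalar.
#' @export
r_squared <- function(net, x, y = NULL, space = NULL) {
  if (inherits(x, "chem_dataset")) {
    y <- x$values
    x <- feature_matrix(x, space)
  }
  if (length(y) < 2L || stats::var(y) == 0) {
    stop("R^2 is undefined for fewer than two observations or a constant response")
  }
  pred <- predict(net, x)
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Five-fold cross-validation over an architecture menu
#'
#' Randomly partitions the data into five folds (reproducibly under
#' \code{fold_seed}; fold membership depends only on the number of rows and
#' the seed), trains each architecture on four folds and evaluates the test
#' R-squared on the held-out fold.
#'
#' @param x feature matrix or \code{\link{chem_dataset}}.
#' @param y responses (from the dataset if omitted).
#' @param architectures list of hidden-layer width vectors.
#' @param space required when \code{x} is a dataset.
#' @param fold_seed seed for the fold assignment.
#' @param train_seed seed for each training run.
#' @param ... passed to \code{\link{mlp_fit}}.
#' @return list of class \code{"mlp_cv"}: matrix \code{r2} (architectures by
#'   folds), per-architecture means \code{t_rcv2}, the best mean, the overall
#'   maximum \code{t_rmax2}, and the fold assignment.
#' @export
mlp_cross_validate <- function(x, y = NULL, architectures = list(8L, 16L),
                               space = NULL, fold_seed = 1L, train_seed = 1L, ...) {
  if (inherits(x, "chem_dataset")) {
    y <- x$values
    x <- feature_matrix(x, space)
  }
  n <- nrow(x)
  stopifnot(n >= 5L)
  set.seed(fold_seed)
  fold <- sample(rep_len(1:5, n))
  r2 <- matrix(NA_real_, length(architectures), 5L)
  for (j in seq_along(architectures)) {
    for (i in 1:5) {
      tr <- fold != i
      net <- mlp_fit(x[tr, , drop = FALSE], y[tr], hidden = architectures[[j]],
                     seed = train_seed, ...)
      r2[j, i] <- r_squared(net, x[!tr, , drop = FALSE], y[!tr])
    }
  }
  t_rcv2 <- rowMeans(r2)
  structure(list(r2 = r2, t_rcv2 = t_rcv2,
                 best = max(t_rcv2), t_rmax2 = max(r2),
                 fold = fold, architectures = architectures),
            class = "mlp_cv")
}

#' @export
print.mlp_cv <- function(x, ...) {
  cat("five-fold cross-validation:\n")
  for (j in seq_along(x$architectures)) {
    cat(sprintf("  hidden (%s): mean test R^2 %.4f\n",
                paste(x$architectures[[j]], collapse = ","), x$t_rcv2[j]))
  }
  cat(sprintf("  best mean %.4f, overall max %.4f\n", x$best, x$t_rmax2))
  invisible(x)
}

#' Reduce a network's input layer to a specification's active descriptors
#'
#' Drops the input nodes for edge-configurations and fringe-tree codes that
#' the specification does not allow.  On any graph satisfying the
#' specification those descriptors are zero, so the reduced network computes
#' the same output while the inversion MILP carries far fewer integer
#' variables.
#'
#' @param net an \code{"mlp_net"} trained against \code{space}.
#' @param space the \code{\link{descriptor_space}} the network was trained on.
#' @param spec a \code{\link{target_spec}} whose \code{gamma_int} and fringe
#'   sets are subsets of the space's.
#' @return list with the reduced \code{net} and reduced \code{space}.
#' @export
reduce_inputs <- function(net, space, spec) {
  if (!all(spec$chem$gamma_int %in% space$gamma_int)) {
    stop("specification uses edge-configurations absent from the descriptor space: ",
         paste(setdiff(spec$chem$gamma_int, space$gamma_int), collapse = "; "))
  }
  if (!all(spec$chem$f_star %in% space$fringe_set)) {
    stop("specification uses fringe codes absent from the descriptor space: ",
         paste(setdiff(spec$chem$f_star, space$fringe_set), collapse = "; "))
  }
  keep_gamma <- space$gamma_int %in% spec$chem$gamma_int
  keep_f <- space$fringe_set %in% spec$chem$f_star
  rspace <- descriptor_space(space$lambda_int, space$lambda_ex,
                             space$gamma_int[keep_gamma],
                             space$fringe_set[keep_f],
                             space$rho, space$table)
  keep <- space$slot_names %in% rspace$slot_names
  rnet <- net
  rnet$weights[[1L]] <- net$weights[[1L]][keep, , drop = FALSE]
  rnet$architecture[1L] <- sum(keep)
  rnet$slot_names <- space$slot_names[keep]
  rnet$fitted <- NULL; rnet$y <- NULL
  list(net = rnet, space = rspace)
}

#' Serialize a trained network (with its descriptor space) to JSON
#'
#' Weights are written in plain decimal text at full precision, together with
#' the descriptor-space definition, so the inversion step is self-contained.
#'
#' @param net an \code{"mlp_net"}.
#' @param space the \code{\link{descriptor_space}} it consumes.
#' @param path output path.
#' @export
write_mlp <- function(net, space, path) {
  obj <- list(architecture = net$architecture,
              weights = net$weights,
              biases = net$biases,
              descriptor_space = list(
                lambda_int = space$lambda_int, lambda_ex = space$lambda_ex,
                gamma_int = space$gamma_int, fringe_set = space$fringe_set,
                rho = space$rho,
                elements = list(symbol = space$table$symbol,
                                valence = space$table$valence,
                                mass10 = space$table$mass10)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a serialized network and its descriptor space
#'
#' @param path JSON file written by \code{\link{write_mlp}}.
#' @return list with \code{net} and \code{space}.
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ds <- obj$descriptor_space
  tab <- element_table(ds$elements$symbol, ds$elements$valence,
                       ds$elements$mass10 / 10 + 0.001)
  tab$mass10 <- as.integer(ds$elements$mass10)
  space <- descriptor_space(ds$lambda_int, ds$lambda_ex, ds$gamma_int,
                            ds$fringe_set, ds$rho, tab)
  W <- lapply(obj$weights, function(w) {
    w <- as.matrix(w)
    storage.mode(w) <- "double"
    w
  })
  b <- obj$biases
  if (is.matrix(b)) b <- lapply(seq_len(nrow(b)), function(i) b[i, ])
  net <- structure(list(weights = W, biases = b,
                        architecture = as.integer(obj$architecture),
                        slot_names = space$slot_names),
                   class = "mlp_net")
  list(net = net, space = space)
}
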