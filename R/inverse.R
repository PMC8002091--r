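# Stage 4: the inversion MILP.  One instance jointly encodes
#   (i)   construction of the interior from the seed graph: integer path
#         lengths realized by prefix-activated vertex slots, leaf-path slots
#         at seed vertices and internal path vertices;
#   (ii)  element / fringe-code / bond-multiplicity assignment;
#   (iii) descriptor counting as linear sums of the assignment binaries; and
#   (iv)  the ReLU forward pass via big-M constraints with per-neuron bounds
#         propagated from the descriptor boxes,
# so that integer-feasible points decode to specification-conforming chemical
# graphs whose predicted property lies in [y* - eps, y* + eps].

# ReLU network encoding on top of existing input variables.
# Returns the index of the output variable.
milp_encode_network <- function(m, net, input_idx) {
  lo <- m$lb[input_idx]; hi <- m$ub[input_idx]
  L <- length(net$weights)
  a_idx <- input_idx; a_lo <- lo; a_hi <- hi
  for (l in seq_len(L)) {
    W <- net$weights[[l]]; b <- net$biases[[l]]
    pl <- ncol(W)
    z_lo <- numeric(pl); z_hi <- numeric(pl)
    for (j in seq_len(pl)) {
      w <- W[, j]
      z_lo[j] <- b[j] + sum(pmin(w * a_lo, w * a_hi))
      z_hi[j] <- b[j] + sum(pmax(w * a_lo, w * a_hi))
    }
    if (l < L) {
      h_idx <- integer(pl)
      for (j in seq_len(pl)) {
        w <- W[, j]
        if (z_hi[j] <= 0) {                       # neuron provably off
          h_idx[j] <- milp_add_var(m, sprintf("h%d_%d", l, j), 0, 0)
        } else if (z_lo[j] >= 0) {                # provably linear
          h_idx[j] <- milp_add_var(m, sprintf("h%d_%d", l, j), z_lo[j], z_hi[j])
          milp_add_con(m, c(h_idx[j], a_idx), c(1, -w), b[j], b[j])
        } else {
          h_idx[j] <- milp_add_var(m, sprintf("h%d_%d", l, j), 0, z_hi[j])
          s <- milp_add_var(m, sprintf("s%d_%d", l, j), 0, 1, integer = TRUE)
          # h >= z
          milp_add_con(m, c(h_idx[j], a_idx), c(1, -w), b[j], Inf)
          # h <= z - z_lo (1 - s)  <=>  h - z - z_lo s <= -z_lo
          milp_add_con(m, c(h_idx[j], a_idx, s), c(1, -w, -z_lo[j]),
                       -Inf, b[j] - z_lo[j])
          # h <= z_hi s
          milp_add_con(m, c(h_idx[j], s), c(1, -z_hi[j]), -Inf, 0)
        }
      }
      a_idx <- h_idx
      a_lo <- pmax(z_lo, 0); a_hi <- pmax(z_hi, 0)
    } else {
      out <- milp_add_var(m, "out", z_lo[1L], z_hi[1L])
      milp_add_con(m, c(out, a_idx), c(1, -W[, 1L]), b[1L], b[1L])
      return(out)
    }
  }
}

#' Evaluate the MILP encoding of a network at a fixed input
#'
#' Builds the big-M encoding of the forward pass with all inputs fixed to
#' \code{x} and solves it; the result must agree with \code{predict} up to
#' solver tolerance.  Exists as the unit contract for the encoding used in
#' \code{\link{formulate_inverse}}.
#'
#' @param net an \code{"mlp_net"}.
#' @param x numeric input vector (length K), or a matrix of row inputs that
#'   are evaluated in one solver call.
#' @param input_box optional 2-row matrix of (lower, upper) input bounds used
#'   for big-M propagation; defaults to the fixed values themselves widened to
#'   an interval around each coordinate.
#' @return numeric vector of MILP-computed outputs.
#' @export
encode_forward_pass <- function(net, x, input_box = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  K <- net$architecture[1L]
  stopifnot(ncol(x) == K)
  probs <- lapply(seq_len(nrow(x)), function(r) {
    m <- milp_new()
    lo <- if (is.null(input_box)) pmin(x[r, ], 0) - 1 else input_box[1L, ]
    hi <- if (is.null(input_box)) pmax(x[r, ], 0) + 1 else input_box[2L, ]
    inp <- milp_add_vars(m, paste0("x", seq_len(K)), lo, hi)
    milp_encode_network(m, net, inp)
    # pin the inputs by equality so the big-M constraints (built from the
    # box bounds) are what determines the output
    for (j in seq_len(K)) milp_add_con(m, inp[j], 1, x[r, j], x[r, j])
    m
  })
  # the output is the last variable of each instance
  res <- solve_milp(probs)
  vapply(seq_along(probs), function(k) {
    if (res[[k]]$status != "optimal") stop("forward-pass MILP not solved: ", res[[k]]$status)
    res[[k]]$x[probs[[k]]$n]
  }, numeric(1))
}

# ---------------------------------------------------------------------------

#' Formulate the inversion MILP for a target specification
#'
#' @param spec a \code{\link{target_spec}}.
#' @param net reduced \code{"mlp_net"} (see \code{\link{reduce_inputs}}).
#' @param space the matching reduced \code{\link{descriptor_space}}.
#' @param y_star target predicted value.
#' @param eps tolerance: the output is constrained to
#'   \code{[y_star - eps, y_star + eps]}.
#' @return object of class \code{"milp_instance"}: the problem, variable
#'   maps, and a \code{decode} closure turning a solution vector into a
#'   \code{\link{chem_graph}}.
#' @export
formulate_inverse <- function(spec, net, space, y_star, eps = 1e-5) {
  if (net$architecture[1L] != space$K) {
    stop("network input width does not match the descriptor space")
  }
  if (!all(spec$chem$lambda_int %in% space$lambda_int)) {
    stop("specification allows interior elements missing from the descriptor space")
  }
  if (!setequal(spec$chem$f_star, space$fringe_set) &&
      !all(spec$chem$f_star %in% space$fringe_set)) {
    stop("specification fringe codes missing from the descriptor space")
  }
  it <- spec$interior; ch <- spec$chem; seed <- spec$seed; tab <- spec$table
  info <- spec_fringe_info(spec)
  p <- seed$n; mE <- nrow(seed$edges)
  n_star <- ch$n_star
  m <- milp_new()

  # ---- structural variables ----------------------------------------------
  ge <- which(seed$classes %in% c("ge1", "ge2"))
  S <- integer(mE)                      # internal slots per seed edge
  u_var <- vector("list", mE)
  use_var <- rep(NA_integer_, mE)
  for (k in seq_len(mE)) {
    if (k %in% ge) {
      S[k] <- max(0L, it$l_ub[k] - 1L)
      if (S[k] > 0L) {
        u_var[[k]] <- milp_add_vars(m, sprintf("u[%d,%d]", k, seq_len(S[k])), 0, 1, TRUE)
        for (s in seq_len(S[k] - 1L)) {
          milp_add_con(m, c(u_var[[k]][s], u_var[[k]][s + 1L]), c(1, -1), 0, Inf)
        }
      }
    } else if (seed$classes[k] == "e01") {
      use_var[k] <- milp_add_var(m, sprintf("use[%d]", k), 0, 1, TRUE)
    }
  }
  # path length expressions and bounds
  len_expr <- vector("list", mE)
  for (k in seq_len(mE)) {
    len_expr[[k]] <- if (k %in% ge) {
      expr_new(u_var[[k]], rep(1, S[k]), 1)
    } else if (seed$classes[k] == "e01") {
      expr_new(use_var[k], 1, 0)
    } else expr_new(const = 1)
    milp_con_expr(m, len_expr[[k]], it$l_lb[k], it$l_ub[k])
  }
  for (sc in spec$side) {
    e <- expr_new()
    for (nm in names(sc$coef)) {
      k <- match(nm, seed$edge_names)
      e <- expr_add(e, expr_scale(len_expr[[k]], sc$coef[[nm]]))
    }
    if (sc$op == "<=") milp_con_expr(m, e, -Inf, sc$rhs)
    else if (sc$op == ">=") milp_con_expr(m, e, sc$rhs, Inf)
    else milp_con_expr(m, e, sc$rhs, sc$rhs)
  }
  # simplicity for parallel seed edges: at most one realized with length 1
  pair_key <- paste(pmin(seed$edges[, 1L], seed$edges[, 2L]),
                    pmax(seed$edges[, 1L], seed$edges[, 2L]))
  for (pk in unique(pair_key[duplicated(pair_key)])) {
    ks <- which(pair_key == pk)
    e <- expr_new()
    for (k in ks) {
      e <- expr_add(e, switch(seed$classes[k],
        ge2 = expr_new(),
        ge1 = if (S[k] > 0L) expr_new(u_var[[k]][1L], -1, 1) else expr_new(const = 1),
        e01 = expr_new(use_var[k], 1, 0),
        eq1 = expr_new(const = 1)))
    }
    milp_con_expr(m, e, -Inf, 1)
  }
  # dropping e01 edges must not disconnect the seed
  e01 <- which(seed$classes == "e01")
  if (length(e01)) {
    subs <- expand.grid(rep(list(c(FALSE, TRUE)), length(e01)))
    for (r in seq_len(nrow(subs))) {
      drop_set <- e01[as.logical(subs[r, ])]
      if (!length(drop_set)) next
      l_test <- rep(1L, mE); l_test[drop_set] <- 0L
      if (!seed_connected(seed, l_test)) {
        milp_add_con(m, use_var[drop_set], rep(1, length(drop_set)), 1, Inf)
      }
    }
  }

  # ---- vertex and edge slots ---------------------------------------------
  # vertex slot table: kind seed/path/leaf with owners
  vs <- data.frame(kind = character(0), k = integer(0), s = integer(0),
                   anchor = integer(0), q = integer(0), stringsAsFactors = FALSE)
  add_vs <- function(kind, k = NA_integer_, s = NA_integer_,
                     anchor = NA_integer_, q = NA_integer_) {
    vs[nrow(vs) + 1L, ] <<- list(kind, k, s, anchor, q)
    nrow(vs)
  }
  for (v in seq_len(p)) add_vs("seed", anchor = v)
  for (k in ge) for (s in seq_len(S[k])) add_vs("path", k, s)
  # leaf slots at seed vertices
  w_var <- list()                       # keyed by anchor slot id
  leaf_sets <- list()                   # anchor slot id -> vertex slot ids
  for (v in seq_len(p)) {
    if (it$v_bl_ub[v] >= 1L && it$v_ch_ub[v] >= 1L) {
      Q <- it$v_ch_ub[v]
      ids <- integer(Q)
      for (q in seq_len(Q)) ids[q] <- add_vs("leaf", anchor = v, q = q)
      leaf_sets[[as.character(v)]] <- ids
    }
  }
  for (k in ge) for (s in seq_len(S[k])) {
    if (it$bl_ub[k] >= 1L && it$ch_ub[k] >= 1L) {
      Q <- it$ch_ub[k]
      aid <- which(vs$kind == "path" & vs$k == k & vs$s == s)
      ids <- integer(Q)
      for (q in seq_len(Q)) ids[q] <- add_vs("leaf", k = k, anchor = aid, q = q)
      leaf_sets[[as.character(aid)]] <- ids
    }
  }
  NV <- nrow(vs)
  # activity expression per vertex slot
  act <- vector("list", NV)
  for (i in seq_len(NV)) {
    act[[i]] <- switch(vs$kind[i],
      seed = expr_new(const = 1),
      path = expr_new(u_var[[vs$k[i]]][vs$s[i]], 1, 0),
      leaf = NULL)   # filled after w vars exist
  }
  for (key in names(leaf_sets)) {
    ids <- leaf_sets[[key]]
    wv <- milp_add_vars(m, sprintf("w[%s,%d]", key, seq_along(ids)), 0, 1, TRUE)
    w_var[[key]] <- wv
    for (q in seq_along(ids)[-1L]) {
      milp_add_con(m, c(wv[q - 1L], wv[q]), c(1, -1), 0, Inf)
    }
    for (q in seq_along(ids)) act[[ids[q]]] <- expr_new(wv[q], 1, 0)
    anchor_slot <- ids[1L]
    anc <- vs$anchor[anchor_slot]
    if (vs$kind[anchor_slot] == "leaf" && !is.na(vs$k[anchor_slot])) {
      # anchored at a path slot: attachment implies the slot is active
      aid <- anc
      milp_con_expr(m, expr_add(expr_new(wv[1L], 1, 0), expr_scale(act[[aid]], -1)), -Inf, 0)
    }
  }
  # leaf-path count/length bounds at seed vertices
  for (v in seq_len(p)) {
    key <- as.character(v)
    if (!is.null(w_var[[key]])) {
      wv <- w_var[[key]]
      milp_add_con(m, wv[1L], 1, it$v_bl_lb[v], it$v_bl_ub[v])
      if (it$v_ch_lb[v] >= 1L) {
        # length >= v_ch_lb when a path is attached
        milp_add_con(m, wv, rep(1, length(wv)) - c(it$v_ch_lb[v], rep(0, length(wv) - 1L)), 0, Inf)
      }
    } else if (it$v_bl_lb[v] >= 1L) {
      milp_add_con(m, integer(0), numeric(0), 1, Inf)   # unsatisfiable
    }
  }
  # per-edge leaf-path bounds
  for (k in ge) {
    aids <- which(vs$kind == "path" & vs$k == k)
    heads <- integer(0); all_w <- list()
    for (aid in aids) {
      key <- as.character(aid)
      if (!is.null(w_var[[key]])) { heads <- c(heads, w_var[[key]][1L]); all_w[[key]] <- w_var[[key]] }
    }
    if (length(heads)) {
      milp_add_con(m, heads, rep(1, length(heads)), it$bl_lb[k], it$bl_ub[k])
      if (it$ch_lb[k] >= 1L) {
        anyq <- milp_add_var(m, sprintf("anyQ[%d]", k), 0, 1, TRUE)
        for (hv in heads) milp_add_con(m, c(anyq, hv), c(1, -1), 0, Inf)
        deep <- vapply(all_w, function(wv) {
          if (length(wv) >= it$ch_lb[k]) wv[it$ch_lb[k]] else NA_integer_
        }, integer(1))
        deep <- deep[!is.na(deep)]
        if (length(deep)) milp_add_con(m, c(deep, anyq), c(rep(1, length(deep)), -1), 0, Inf)
        else milp_add_con(m, anyq, 1, 0, 0)
      }
    } else if (it$bl_lb[k] >= 1L) {
      milp_add_con(m, integer(0), numeric(0), 1, Inf)
    }
  }

  # edge slot table with activity expressions and endpoints
  es_u <- integer(0); es_v <- integer(0); es_owner <- integer(0)
  es_act <- list()
  add_es <- function(iu, iv, owner, act_expr) {
    es_u <<- c(es_u, iu); es_v <<- c(es_v, iv); es_owner <<- c(es_owner, owner)
    es_act[[length(es_act) + 1L]] <<- act_expr
    length(es_u)
  }
  path_slot <- function(k, s) which(vs$kind == "path" & vs$k == k & vs$s == s)
  for (k in seq_len(mE)) {
    iu <- seed$edges[k, 1L]; iv <- seed$edges[k, 2L]
    cls <- seed$classes[k]
    if (cls == "eq1") add_es(iu, iv, k, expr_new(const = 1))
    else if (cls == "e01") add_es(iu, iv, k, expr_new(use_var[k], 1, 0))
    else {
      if (it$l_lb[k] <= 1L) {
        add_es(iu, iv, k, expr_new(u_var[[k]][1L], -1, 1))
      }
      if (S[k] > 0L) {
        add_es(iu, path_slot(k, 1L), k, expr_new(u_var[[k]][1L], 1, 0))
        for (s in seq_len(S[k])[-1L]) {
          add_es(path_slot(k, s - 1L), path_slot(k, s), k, expr_new(u_var[[k]][s], 1, 0))
        }
        for (s in seq_len(S[k])) {
          nxt <- if (s < S[k]) u_var[[k]][s + 1L] else NA_integer_
          e <- if (is.na(nxt)) expr_new(u_var[[k]][s], 1, 0)
               else expr_new(c(u_var[[k]][s], nxt), c(1, -1), 0)
          add_es(path_slot(k, s), iv, k, e)
        }
      }
    }
  }
  for (key in names(leaf_sets)) {
    ids <- leaf_sets[[key]]
    wv <- w_var[[key]]
    anc0 <- if (vs$kind[ids[1L]] == "leaf" && is.na(vs$k[ids[1L]])) vs$anchor[ids[1L]] else vs$anchor[ids[1L]]
    prev <- anc0
    for (q in seq_along(ids)) {
      add_es(prev, ids[q], 0L, expr_new(wv[q], 1, 0))
      prev <- ids[q]
    }
  }
  NE <- length(es_u)

  # bond multiplicity binaries per edge slot
  b2 <- milp_add_vars(m, sprintf("b2[%d]", seq_len(NE)), 0, 1, TRUE)
  b3 <- milp_add_vars(m, sprintf("b3[%d]", seq_len(NE)), 0, 1, TRUE)
  for (f in seq_len(NE)) {
    milp_con_expr(m, expr_add(expr_new(c(b2[f], b3[f]), c(1, 1), 0),
                              expr_scale(es_act[[f]], -1)), -Inf, 0)
  }
  for (k in seq_len(mE)) {
    rows <- which(es_owner == k)
    milp_add_con(m, b2[rows], rep(1, length(rows)), it$bd2_lb[k], it$bd2_ub[k])
    milp_add_con(m, b3[rows], rep(1, length(rows)), it$bd3_lb[k], it$bd3_ub[k])
  }

  # interior degree expression per vertex slot
  ideg <- vector("list", NV)
  for (i in seq_len(NV)) ideg[[i]] <- expr_new()
  for (f in seq_len(NE)) {
    ideg[[es_u[f]]] <- expr_add(ideg[[es_u[f]]], es_act[[f]])
    ideg[[es_v[f]]] <- expr_add(ideg[[es_v[f]]], es_act[[f]])
  }

  # ---- element / fringe / symbol assignment ------------------------------
  x_var <- vector("list", NV)           # element binaries
  t_var <- vector("list", NV)           # fringe-code binaries
  cs_var <- vector("list", NV)          # chemical-symbol binaries
  elem_sets <- vector("list", NV)
  code_sets <- vector("list", NV)
  sym_sets <- vector("list", NV)        # per-slot feasible chemical symbols
  sym_set <- ch$lambda_dg_int
  sym_parts <- lapply(sym_set, split_symbol)
  sym_elem <- vapply(sym_parts, `[[`, character(1), "elem")
  sym_deg <- vapply(sym_parts, `[[`, integer(1), "deg")
  # degree range attainable by each slot kind while active
  slot_ideg_range <- function(i) {
    switch(vs$kind[i],
      seed = {
        v <- vs$anchor[i]
        ks <- which(seed$edges[, 1L] == v | seed$edges[, 2L] == v)
        lo <- sum(seed$classes[ks] != "e01")
        hi <- length(ks) + (it$v_bl_ub[v] >= 1L && it$v_ch_ub[v] >= 1L)
        c(lo, hi)
      },
      path = c(2L, 2L + (it$bl_ub[vs$k[i]] >= 1L && it$ch_ub[vs$k[i]] >= 1L)),
      leaf = c(1L, 2L))
  }
  for (i in seq_len(NV)) {
    elems <- if (vs$kind[i] == "seed") intersect(ch$lambda_star[[vs$anchor[i]]], ch$lambda_int) else ch$lambda_int
    elem_sets[[i]] <- elems
    if (!length(elems)) milp_add_con(m, integer(0), numeric(0), 1, Inf)
    x_var[[i]] <- milp_add_vars(m, sprintf("x[%d,%s]", i, elems), 0, 1, TRUE)
    milp_con_expr(m, expr_add(expr_new(x_var[[i]], rep(1, length(elems)), 0),
                              expr_scale(act[[i]], -1)), 0, 0)
    codes <- if (vs$kind[i] == "seed") ch$fringe_v[[vs$anchor[i]]] else ch$fringe_e
    codes <- codes[vapply(codes, function(cd) info[[cd]]$root_elem %in% elems, logical(1))]
    code_sets[[i]] <- codes
    if (!length(codes)) milp_add_con(m, integer(0), numeric(0), 1, Inf)
    t_var[[i]] <- milp_add_vars(m, sprintf("t[%d,%d]", i, seq_along(codes)), 0, 1, TRUE)
    milp_con_expr(m, expr_add(expr_new(t_var[[i]], rep(1, length(codes)), 0),
                              expr_scale(act[[i]], -1)), 0, 0)
    for (ci in seq_along(codes)) {
      a <- info[[codes[ci]]]$root_elem
      milp_add_con(m, c(t_var[[i]][ci], x_var[[i]][match(a, elems)]), c(1, -1), -Inf, 0)
    }
    # mandatory height-rho fringe when the interior degree is exactly 1
    max_ideg <- length(ideg[[i]]$coef) + ideg[[i]]$const
    if (max_ideg >= 1L) {
      short <- which(vapply(codes, function(cd) info[[cd]]$height < spec$rho, logical(1)))
      e <- expr_add(if (length(short)) expr_new(t_var[[i]][short], rep(1, length(short)), 0) else expr_new(),
                    expr_scale(ideg[[i]], -1), act[[i]])
      milp_con_expr(m, e, -Inf, 0)
    }
    # feasible symbols for this slot: element allowed, degree within the
    # slot's attainable interior-degree plus fringe root-degree range
    rd <- vapply(code_sets[[i]], function(cd) info[[cd]]$root_deg, numeric(1))
    rng <- slot_ideg_range(i)
    keep_sym <- sym_elem %in% elems &
      sym_deg >= rng[1L] & sym_deg <= min(4L, rng[2L] + max(c(rd, 0)))
    sym_sets[[i]] <- sym_set[keep_sym]
    if (!length(sym_sets[[i]])) milp_add_con(m, integer(0), numeric(0), 1, Inf)
    cs_var[[i]] <- milp_add_vars(m, sprintf("cs[%d,%s]", i, sym_sets[[i]]), 0, 1, TRUE)
    milp_con_expr(m, expr_add(expr_new(cs_var[[i]], rep(1, length(sym_sets[[i]])), 0),
                              expr_scale(act[[i]], -1)), 0, 0)
    loc_elem <- sym_elem[keep_sym]; loc_deg <- sym_deg[keep_sym]
    for (a in elems) {
      js <- which(loc_elem == a)
      xi <- x_var[[i]][match(a, elems)]
      milp_add_con(m, c(cs_var[[i]][js], xi), c(rep(1, length(js)), -1), 0, 0)
    }
    # degree consistency: sum deg(mu) cs = interior degree + fringe root degree
    e <- expr_add(expr_new(cs_var[[i]], loc_deg, 0),
                  expr_scale(ideg[[i]], -1),
                  expr_new(t_var[[i]], -rd, 0))
    milp_con_expr(m, e, 0, 0)
    # valence: interior bond sum + fringe root bonds <= valence
    rb <- vapply(code_sets[[i]], function(cd) info[[cd]]$root_beta, numeric(1))
    inc <- which(es_u == i | es_v == i)
    e <- expr_new(t_var[[i]], rb, 0)
    for (f in inc) e <- expr_add(e, es_act[[f]], expr_new(c(b2[f], b3[f]), c(1, 2), 0))
    e <- expr_add(e, expr_new(x_var[[i]], -elem_valence(tab, elems), 0))
    milp_con_expr(m, e, -Inf, 0)
  }
  # interior-degree indicators (for the dg_int descriptors)
  z2 <- vector("list", NV)
  for (i in seq_len(NV)) {
    z2[[i]] <- milp_add_vars(m, sprintf("z2[%d,%d]", i, 0:4), 0, 1, TRUE)
    milp_con_expr(m, expr_add(expr_new(z2[[i]], rep(1, 5), 0), expr_scale(act[[i]], -1)), 0, 0)
    milp_con_expr(m, expr_add(expr_new(z2[[i]], 0:4, 0), expr_scale(ideg[[i]], -1)), 0, 0)
  }
  # hydro-degree indicators for the interior roots
  hv <- vector("list", NV)
  for (i in seq_len(NV)) {
    hv[[i]] <- milp_add_vars(m, sprintf("h[%d,%d]", i, 0:3), 0, 1, TRUE)
    milp_con_expr(m, expr_add(expr_new(hv[[i]], rep(1, 4), 0), expr_scale(act[[i]], -1)), 0, 0)
    rb <- vapply(code_sets[[i]], function(cd) info[[cd]]$root_beta, numeric(1))
    inc <- which(es_u == i | es_v == i)
    e <- expr_add(expr_new(hv[[i]], 0:3, 0),
                  expr_new(x_var[[i]], -elem_valence(tab, elem_sets[[i]]), 0),
                  expr_new(t_var[[i]], rb, 0))
    for (f in inc) e <- expr_add(e, es_act[[f]], expr_new(c(b2[f], b3[f]), c(1, 2), 0))
    milp_con_expr(m, e, 0, 0)
  }

  # directed edge-configuration binaries
  gam_parts <- strsplit(ch$gamma_int, ",", fixed = TRUE)
  dir_pairs <- list()
  for (gp in gam_parts) {
    dir_pairs[[length(dir_pairs) + 1L]] <- c(gp[1L], gp[2L], gp[3L])
    if (gp[1L] != gp[2L]) dir_pairs[[length(dir_pairs) + 1L]] <- c(gp[2L], gp[1L], gp[3L])
  }
  dp_mu <- vapply(dir_pairs, `[`, character(1), 1L)
  dp_xi <- vapply(dir_pairs, `[`, character(1), 2L)
  dp_m <- as.integer(vapply(dir_pairs, `[`, character(1), 3L))
  dp_canon <- vapply(seq_along(dir_pairs), function(j) {
    ra <- symbol_rank(dp_mu[j], tab); rb <- symbol_rank(dp_xi[j], tab)
    if (ra <= rb) paste(dp_mu[j], dp_xi[j], dp_m[j], sep = ",")
    else paste(dp_xi[j], dp_mu[j], dp_m[j], sep = ",")
  }, character(1))
  y_var <- vector("list", NE)
  for (f in seq_len(NE)) {
    keep <- dp_mu %in% sym_sets[[es_u[f]]] & dp_xi %in% sym_sets[[es_v[f]]]
    if (!any(keep)) {
      # no admissible configuration: the edge slot can never be active
      milp_con_expr(m, es_act[[f]], 0, 0)
    }
    y_var[[f]] <- list(idx = milp_add_vars(m, sprintf("y[%d,%d]", f, which(keep)), 0, 1, TRUE),
                       which = which(keep))
    idx <- y_var[[f]]$idx; wh <- y_var[[f]]$which
    milp_con_expr(m, expr_add(expr_new(idx, rep(1, length(idx)), 0),
                              expr_scale(es_act[[f]], -1)), 0, 0)
    for (mu in unique(dp_mu[wh])) {
      js <- which(dp_mu[wh] == mu)
      milp_add_con(m, c(idx[js], cs_var[[es_u[f]]][match(mu, sym_sets[[es_u[f]]])]),
                   c(rep(1, length(js)), -1), -Inf, 0)
    }
    for (xi in unique(dp_xi[wh])) {
      js <- which(dp_xi[wh] == xi)
      milp_add_con(m, c(idx[js], cs_var[[es_v[f]]][match(xi, sym_sets[[es_v[f]]])]),
                   c(rep(1, length(js)), -1), -Inf, 0)
    }
    # multiplicity partition
    js1 <- which(dp_m[wh] == 1L); js2 <- which(dp_m[wh] == 2L); js3 <- which(dp_m[wh] == 3L)
    e1 <- expr_add(if (length(js1)) expr_new(idx[js1], rep(1, length(js1)), 0) else expr_new(),
                   expr_scale(es_act[[f]], -1),
                   expr_new(c(b2[f], b3[f]), c(1, 1), 0))
    milp_con_expr(m, e1, 0, 0)
    milp_con_expr(m, expr_add(if (length(js2)) expr_new(idx[js2], rep(1, length(js2)), 0) else expr_new(),
                              expr_new(b2[f], -1, 0)), 0, 0)
    milp_con_expr(m, expr_add(if (length(js3)) expr_new(idx[js3], rep(1, length(js3)), 0) else expr_new(),
                              expr_new(b3[f], -1, 0)), 0, 0)
  }

  # ---- descriptor variables ----------------------------------------------
  nint_expr <- expr_new(const = 0)
  for (i in seq_len(NV)) nint_expr <- expr_add(nint_expr, act[[i]])
  nv_ex <- function(i) vapply(code_sets[[i]], function(cd) info[[cd]]$nv_ex, numeric(1))
  n_expr <- nint_expr
  for (i in seq_len(NV)) n_expr <- expr_add(n_expr, expr_new(t_var[[i]], nv_ex(i), 0))
  milp_con_expr(m, nint_expr, it$n_int_lb, it$n_int_ub)
  milp_con_expr(m, n_expr, ch$n_lb, n_star)

  dsc <- integer(space$K)
  names(dsc) <- space$slot_names
  masses <- elem_mass10(tab, tab$symbol)
  def_dsc <- function(nm, e, lb = 0, ub = n_star) {
    v <- milp_add_var(m, nm, lb, ub)
    milp_con_expr(m, expr_add(expr_new(v, -1, 0), e), 0, 0)
    dsc[nm] <<- v
    v
  }
  def_dsc("n", n_expr, max(1, ch$n_lb), n_star)
  def_dsc("n_int", nint_expr, max(1, it$n_int_lb), it$n_int_ub)
  # ms_avg: select n via indicator binaries, then bound the average per value
  ms_lo <- min(elem_mass10(tab, unique(c(ch$lambda_int, fringe_elements(ch$f_star)))))
  ms_hi <- max(elem_mass10(tab, unique(c(ch$lambda_int, fringe_elements(ch$f_star)))))
  ms_v <- milp_add_var(m, "ms_avg", ms_lo, ms_hi)
  dsc["ms_avg"] <- ms_v
  mass_expr <- expr_new()
  for (i in seq_len(NV)) {
    mass_expr <- expr_add(mass_expr,
      expr_new(x_var[[i]], elem_mass10(tab, elem_sets[[i]]), 0),
      expr_new(t_var[[i]], vapply(code_sets[[i]], function(cd) info[[cd]]$mass_ex, numeric(1)), 0))
  }
  n_vals <- seq(max(1L, ch$n_lb), n_star)
  dn <- milp_add_vars(m, sprintf("nsel[%d]", n_vals), 0, 1, TRUE)
  milp_add_con(m, dn, rep(1, length(dn)), 1, 1)
  milp_con_expr(m, expr_add(expr_new(dn, n_vals, 0), expr_scale(n_expr, -1)), 0, 0)
  for (j in seq_along(n_vals)) {
    # when nsel[j] = 0 the pair must be vacuous: Mass/n_j ranges over
    # [ms_lo/n_j, n_star ms_hi/n_j] while ms stays in [ms_lo, ms_hi]
    M_up <- ms_hi - ms_lo / n_vals[j]
    M_dn <- n_star * ms_hi / n_vals[j] - ms_lo
    e <- expr_add(expr_new(ms_v, 1, 0), expr_scale(mass_expr, -1 / n_vals[j]),
                  expr_new(dn[j], M_up, 0))
    milp_con_expr(m, e, -Inf, M_up)
    e <- expr_add(expr_new(ms_v, 1, 0), expr_scale(mass_expr, -1 / n_vals[j]),
                  expr_new(dn[j], -M_dn, 0))
    milp_con_expr(m, e, -M_dn, Inf)
  }
  ub_int <- it$n_int_ub                    # tight boxes shrink every big-M
  ub_iedge <- it$n_int_ub + mE
  for (d in 1:4) {
    e <- expr_new()
    for (i in seq_len(NV)) {
      js <- which(vapply(sym_sets[[i]], function(mu) split_symbol(mu)$deg, integer(1)) == d)
      if (length(js)) e <- expr_add(e, expr_new(cs_var[[i]][js], rep(1, length(js)), 0))
    }
    def_dsc(paste0("dg_", d), e, 0, ub_int)
  }
  for (d in 1:4) {
    e <- expr_new()
    for (i in seq_len(NV)) e <- expr_add(e, expr_new(z2[[i]][d + 1L], 1, 0))
    def_dsc(paste0("dg_int_", d), e, 0, ub_int)
  }
  for (d in 0:3) {
    e <- expr_new()
    for (i in seq_len(NV)) {
      e <- expr_add(e, expr_new(hv[[i]][d + 1L], 1, 0),
                    expr_new(t_var[[i]],
                             vapply(code_sets[[i]], function(cd) sum(info[[cd]]$hyd_ex == d), numeric(1)), 0))
    }
    def_dsc(paste0("hydg_", d), e)
  }
  def_dsc("bd_int_2", expr_new(b2, rep(1, NE), 0), 0, ub_iedge)
  def_dsc("bd_int_3", expr_new(b3, rep(1, NE), 0), 0, ub_iedge)
  for (a in space$lambda_int) {
    e <- expr_new()
    for (i in seq_len(NV)) {
      j <- match(a, elem_sets[[i]])
      if (!is.na(j)) e <- expr_add(e, expr_new(x_var[[i]][j], 1, 0))
    }
    v <- def_dsc(paste0("na_int_", a), e, 0, ub_int)
    milp_add_con(m, v, 1, named_bound(ch$na_int_lb, a, 0),
                 named_bound(ch$na_int_ub, a, n_star))
  }
  naex_of <- function(i, a) vapply(code_sets[[i]], function(cd) {
    t <- info[[cd]]$template
    sum(t$alpha[-1L] == a)
  }, numeric(1))
  for (a in space$lambda_ex) {
    e <- expr_new()
    for (i in seq_len(NV)) e <- expr_add(e, expr_new(t_var[[i]], naex_of(i, a), 0))
    def_dsc(paste0("na_ex_", a), e, 0, max(0, n_star - max(1L, it$n_int_lb)))
  }
  # whole-graph element bounds
  for (a in names(ch$na_lb)) {
    e <- expr_new()
    for (i in seq_len(NV)) {
      j <- match(a, elem_sets[[i]])
      if (!is.na(j)) e <- expr_add(e, expr_new(x_var[[i]][j], 1, 0))
      e <- expr_add(e, expr_new(t_var[[i]], naex_of(i, a), 0))
    }
    milp_con_expr(m, e, ch$na_lb[[a]], ch$na_ub[[a]])
  }
  # chemical-symbol count bounds
  for (mu in sym_set) {
    e <- expr_new()
    for (i in seq_len(NV)) {
      j <- match(mu, sym_sets[[i]])
      if (!is.na(j)) e <- expr_add(e, expr_new(cs_var[[i]][j], 1, 0))
    }
    milp_con_expr(m, e, named_bound(ch$ns_int_lb, mu, 0),
                  named_bound(ch$ns_int_ub, mu, n_star))
  }
  # edge-configuration counts (+ ac aggregation)
  ec_expr <- list()
  for (gma in space$gamma_int) {
    e <- expr_new()
    for (f in seq_len(NE)) {
      js <- which(dp_canon[y_var[[f]]$which] == gma)
      if (length(js)) e <- expr_add(e, expr_new(y_var[[f]]$idx[js], rep(1, length(js)), 0))
    }
    ec_expr[[gma]] <- e
    v <- def_dsc(paste0("ec_(", gma, ")"), e, 0, ub_iedge)
    if (gma %in% names(ch$ec_int_lb)) {
      milp_add_con(m, v, 1, ch$ec_int_lb[[gma]], ch$ec_int_ub[[gma]])
    } else {
      milp_add_con(m, v, 1, 0, 0)    # configuration not allowed by the spec
    }
  }
  for (ac in names(ch$ac_int_lb)) {
    e <- expr_new()
    for (gma in names(ec_expr)) {
      if (gma %in% names(ch$ec_int_lb) && ec_to_ac(gma, tab) == ac) e <- expr_add(e, ec_expr[[gma]])
    }
    milp_con_expr(m, e, ch$ac_int_lb[[ac]], ch$ac_int_ub[[ac]])
  }
  for (cd in space$fringe_set) {
    e <- expr_new()
    for (i in seq_len(NV)) {
      j <- match(cd, code_sets[[i]])
      if (!is.na(j)) e <- expr_add(e, expr_new(t_var[[i]][j], 1, 0))
    }
    def_dsc(paste0("fc_", cd), e, 0, ub_int)
  }

  # ---- the network and the target ----------------------------------------
  out <- milp_encode_network(m, net, dsc[space$slot_names])
  # the target band is handled through the objective: minimize the gap
  # |out - y*| and accept the optimum iff it is within eps.  Optimizing the
  # gap is vastly easier for branch-and-bound than finding a point inside a
  # thin feasibility band, and the accepted solution set is identical.
  gap <- milp_add_var(m, "target_gap", 0, Inf)
  m$obj[gap] <- 1
  milp_add_con(m, c(gap, out), c(1, -1), -y_star, Inf)
  milp_add_con(m, c(gap, out), c(1, 1), y_star, Inf)

  decode <- local({
    vs_l <- vs; es_u_l <- es_u; es_v_l <- es_v
    es_act_l <- es_act; act_l <- act
    x_l <- x_var; t_l <- t_var; elem_l <- elem_sets; code_l <- code_sets
    b2_l <- b2; b3_l <- b3; info_l <- info; tab_l <- tab
    function(sol) {
      active <- vapply(act_l, function(e) expr_eval(e, sol) > 0.5, logical(1))
      ids <- which(active)
      remap <- match(seq_along(active), ids)
      alpha <- character(length(ids))
      codes <- character(length(ids))
      for (j in seq_along(ids)) {
        i <- ids[j]
        alpha[j] <- elem_l[[i]][which(sol[x_l[[i]]] > 0.5)[1L]]
        codes[j] <- code_l[[i]][which(sol[t_l[[i]]] > 0.5)[1L]]
      }
      edges <- matrix(integer(0), ncol = 2L); beta <- integer(0)
      for (f in seq_along(es_u_l)) {
        if (expr_eval(es_act_l[[f]], sol) > 0.5) {
          edges <- rbind(edges, c(remap[es_u_l[f]], remap[es_v_l[f]]))
          beta <- c(beta, 1L + (sol[b2_l[f]] > 0.5) + 2L * (sol[b3_l[f]] > 0.5))
        }
      }
      fr <- lapply(codes, function(cd) {
        if (info_l[[cd]]$nv_ex > 0L) info_l[[cd]]$template else NULL
      })
      assemble_graph(length(ids), edges, alpha, beta, fr, tab_l)
    }
  })
  structure(list(problem = m, decode = decode, dsc = dsc,
                 out = out, y_star = y_star, eps = eps,
                 spec = spec, net = net, space = space,
                 counts = milp_counts(m)),
            class = "milp_instance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# value of a named bound vector, with a default for absent keys
named_bound <- function(vec, key, default) {
  if (!is.null(vec) && key %in% names(vec)) vec[[key]] else default
}

#' @export
print.milp_instance <- function(x, ...) {
  cat(sprintf("milp_instance: %d variables, %d constraints, target %.6g (eps %.2g)\n",
              x$counts[1L], x$counts[2L], x$y_star, x$eps))
  invisible(x)
}

#' Solve an inversion MILP and decode the result
#'
#' @param instance a \code{"milp_instance"} from \code{\link{formulate_inverse}}.
#' @param time_limit solver time limit (seconds).
#' @return object of class \code{"inference_result"}: \code{status}
#'   (\code{"feasible"}, \code{"infeasible"} or \code{"timeout"}), the decoded
#'   \code{graph}, its recomputed \code{feature_vector}, the \code{predicted}
#'   value and \code{verified} flag.
#' @export
solve_inverse <- function(instance, time_limit = 300) {
  # two-phase: the default search settles most instances quickly; on a
  # timeout, retry with aggressive primal heuristics, which find the thin
  # gap-0 incumbents the default search can miss
  t1 <- min(30, time_limit / 2)
  res <- solve_milp(instance$problem, time_limit = t1)
  if (res$status == "limit") {
    res <- solve_milp(instance$problem, time_limit = time_limit - t1,
                      heuristic_effort = 1.0)
  }
  if (res$status == "infeasible") {
    return(structure(list(status = "infeasible", graph = NULL),
                     class = "inference_result"))
  }
  if (res$status != "optimal" && is.null(res$x)) {
    return(structure(list(status = if (res$status == "limit") "timeout" else res$status,
                          graph = NULL), class = "inference_result"))
  }
  if (res$status == "optimal" && res$fun > instance$eps + 1e-7) {
    # the closest attainable prediction misses the target band
    return(structure(list(status = "infeasible", graph = NULL,
                          best_gap = res$fun), class = "inference_result"))
  }
  if (res$status != "optimal" && res$fun > instance$eps + 1e-7) {
    return(structure(list(status = "timeout", graph = NULL,
                          best_gap = res$fun), class = "inference_result"))
  }
  g <- instance$decode(res$x)
  xv <- feature_vector(g, instance$space)
  pred <- predict(instance$net, xv)
  out <- structure(list(status = "feasible", graph = g, feature_vector = xv,
                        predicted = pred, y_star = instance$y_star,
                        eps = instance$eps,
                        milp_x = res$x),
                   class = "inference_result")
  out$verified <- verify_inference(out, instance$net, instance$space, instance$spec)
  out
}

#' @export
print.inference_result <- function(x, ...) {
  if (x$status != "feasible") cat("inference_result:", x$status, "\n")
  else cat(sprintf("inference_result: feasible, n = %d, predicted %.6g (target %.6g), verified: %s\n",
                   x$graph$n, x$predicted, x$y_star, x$verified))
  invisible(x)
}

#' Independently verify an inference result
#'
#' Recomputes the two-layered decomposition, the feature vector and the
#' forward pass from the decoded graph alone, validates the graph against the
#' specification, and checks that the prediction meets the target tolerance.
#'
#' @param result an \code{"inference_result"} with status \code{"feasible"}.
#' @param net,space the (reduced) predictor and descriptor space used in the
#'   formulation.
#' @param spec the \code{\link{target_spec}}.
#' @param eps target tolerance (defaults to the result's).
#' @return logical; on failure the attribute \code{"diagnosis"} lists reasons.
#' @export
verify_inference <- function(result, net, space, spec, eps = result$eps) {
  bad <- character(0)
  g <- result$graph
  if (is.null(g)) return(structure(FALSE, diagnosis = "no graph"))
  xv <- tryCatch(feature_vector(g, space), error = function(e) NULL)
  if (is.null(xv)) bad <- c(bad, "feature vector not computable in the reduced space")
  else {
    ints <- setdiff(space$slot_names, "ms_avg")
    dif <- which(abs(xv[ints] - result$feature_vector[ints]) > 0)
    if (length(dif)) bad <- c(bad, paste("integer descriptor mismatch:", paste(ints[dif], collapse = ",")))
    if (abs(xv["ms_avg"] - result$feature_vector["ms_avg"]) > 1e-9) bad <- c(bad, "ms_avg mismatch")
    pred <- predict(net, xv)
    if (abs(pred - result$y_star) > eps + 1e-6) {
      bad <- c(bad, sprintf("prediction %.8g misses target %.8g", pred, result$y_star))
    }
  }
  rep <- validate_extension(g, spec)
  if (!rep$is_extension) {
    bad <- c(bad, paste("specification violated:",
                        paste(vapply(rep$violations, `[[`, character(1), "rule"), collapse = ",")))
  }
  structure(length(bad) == 0L, diagnosis = bad)
}

#' Feasibility scan over a grid of target values
#'
#' Formulates and solves one inversion MILP per target value, reporting the
#' feasibility status of each and the extreme feasible targets observed.
#'
#' @param spec a \code{\link{target_spec}}.
#' @param net,space reduced predictor and space.
#' @param y_grid numeric vector of target values.
#' @param eps tolerance per target.
#' @param time_limit per-solve limit.
#' @return list with \code{table} (data frame of y and status) and the
#'   observed feasible range \code{y_range}.
#' @export
feasibility_scan <- function(spec, net, space, y_grid, eps = 1e-5, time_limit = 120) {
  status <- character(length(y_grid))
  for (j in seq_along(y_grid)) {
    inst <- formulate_inverse(spec, net, space, y_grid[j], eps)
    r <- solve_inverse(inst, time_limit = time_limit)
    status[j] <- r$status
  }
  feas <- y_grid[status == "feasible"]
  list(table = data.frame(y = y_grid, status = status),
       y_range = if (length(feas)) range(feas) else c(NA_real_, NA_real_))
}
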