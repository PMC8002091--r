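# Constructive side of the specification DSL: rejection sampling of random
# extensions (a test oracle and fixture source) and exhaustive enumeration of
# the extension set at toy scale (the brute-force oracle for the MILP).

# fringe candidates for one skeleton vertex
fringe_candidates <- function(spec, info, is_seed, seed_id, elem, spare, mandatory) {
  codes <- if (is_seed) spec$chem$fringe_v[[seed_id]] else spec$chem$fringe_e
  keep <- vapply(codes, function(cd) {
    s <- info[[cd]]
    s$root_elem == elem && s$root_beta <= spare &&
      (if (mandatory) s$height == spec$rho else s$height <= spec$rho)
  }, logical(1))
  codes[keep]
}

#' Sample a random extension of a target specification
#'
#' Rejection sampling that follows the construction order: subdivide the seed
#' edges, attach leaf paths, assign elements and bond multiplicities, then
#' attach fringe trees from the candidate sets.  Every vertex of interior
#' degree at most 1 receives a fringe tree of height exactly \code{rho} so
#' that the decomposition of the result reproduces the constructed interior.
#' Each draw is validated with \code{\link{validate_extension}} before it is
#' returned.
#'
#' @param spec a \code{\link{target_spec}}.
#' @param rng_seed optional integer seed.
#' @param attempts attempt budget before giving up.
#' @return a \code{\link{chem_graph}}, or \code{NULL} if no valid extension
#'   was found within the budget.
#' @export
random_extension <- function(spec, rng_seed = NULL, attempts = 400L) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  info <- spec_fringe_info(spec)
  it <- spec$interior; ch <- spec$chem; seed <- spec$seed
  m <- nrow(seed$edges); p <- seed$n
  for (att in seq_len(attempts)) {
    budget <- it$n_int_ub - p
    l <- integer(m)
    ok <- TRUE
    for (k in seq_len(m)) {
      lo <- it$l_lb[k]
      hi <- min(it$l_ub[k], lo + budget + 1L)
      if (lo > hi) { ok <- FALSE; break }
      l[k] <- sample1(seq(lo, hi))
      budget <- budget - max(0L, l[k] - 1L)
      if (budget < 0L) { ok <- FALSE; break }
    }
    if (!ok || !seed_connected(seed, l) || !side_ok(spec, l)) next
    leaf_v <- integer(p)
    for (v in seq_len(p)) {
      want <- sample1(seq(it$v_bl_lb[v], it$v_bl_ub[v]))
      if (want >= 1L) {
        lo <- max(1L, it$v_ch_lb[v]); hi <- min(it$v_ch_ub[v], lo + budget)
        if (lo > hi) { ok <- FALSE; break }
        leaf_v[v] <- sample1(seq(lo, hi))
        budget <- budget - leaf_v[v]
        if (budget < 0L) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    leaf_e <- vector("list", m)
    for (k in seq_len(m)) {
      nslots <- max(0L, l[k] - 1L)
      leaf_e[[k]] <- integer(nslots)
      lo_c <- it$bl_lb[k]; hi_c <- min(it$bl_ub[k], nslots)
      if (lo_c > hi_c) { ok <- FALSE; break }
      cnt <- sample1(seq(lo_c, hi_c))
      if (cnt > 0L) {
        slots <- sample(nslots)[seq_len(cnt)]
        for (s in slots) {
          lo <- 1L; hi <- min(it$ch_ub[k], lo + budget)
          if (lo > hi) { ok <- FALSE; break }
          leaf_e[[k]][s] <- sample1(seq(lo, hi))
          budget <- budget - leaf_e[[k]][s]
        }
        if (!ok) break
        if (it$ch_lb[k] > 0L && max(leaf_e[[k]]) < it$ch_lb[k]) {
          if (it$ch_lb[k] > it$ch_ub[k] || it$ch_lb[k] - max(leaf_e[[k]]) > budget) { ok <- FALSE; break }
          s <- slots[1L]
          budget <- budget - (it$ch_lb[k] - leaf_e[[k]][s])
          leaf_e[[k]][s] <- it$ch_lb[k]
        }
        if (budget < 0L) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    sk <- make_skeleton(spec, l, leaf_v, leaf_e)
    if (sk$n < it$n_int_lb || sk$n > it$n_int_ub) next
    g <- sample_labels(spec, info, sk)
    if (is.null(g)) next
    rep <- validate_extension(g, spec)
    if (rep$is_extension) return(g)
  }
  NULL
}

# assign elements, bonds and fringes on a skeleton at random; NULL on failure
sample_labels <- function(spec, info, sk) {
  it <- spec$interior; ch <- spec$chem; tab <- spec$table
  alpha <- character(sk$n)
  for (i in seq_len(sk$n)) {
    allowed <- if (i <= sk$p) intersect(ch$lambda_star[[i]], ch$lambda_int) else ch$lambda_int
    need <- sk$deg[i] + if (sk$deg[i] <= 1L) 1L else 0L
    allowed <- allowed[elem_valence(tab, allowed) >= need]
    if (!length(allowed)) return(NULL)
    alpha[i] <- allowed[sample.int(length(allowed), 1L)]
  }
  beta <- rep(1L, nrow(sk$edges))
  spare <- elem_valence(tab, alpha) - sk$deg
  reserve <- ifelse(sk$deg <= 1L, 1L, 0L)
  # per seed edge, meet the lower multi-bond bounds then raise a few more
  for (k in seq_len(nrow(spec$seed$edges))) {
    rows <- which(sk$eowner == k)
    for (m in c(2L, 3L)) {
      lbk <- it[[sprintf("bd%d_lb", m)]][k]
      ubk <- it[[sprintf("bd%d_ub", m)]][k]
      have <- sum(beta[rows] == m)
      cand <- rows[beta[rows] == 1L]
      cand <- cand[sample.int(length(cand))]
      for (r in cand) {
        extra <- if (have < lbk) TRUE else (have < ubk && stats::runif(1) < 0.15)
        if (!extra) break
        u <- sk$edges[r, 1L]; v <- sk$edges[r, 2L]
        dm <- m - 1L
        if (spare[u] - reserve[u] >= dm && spare[v] - reserve[v] >= dm) {
          beta[r] <- m
          spare[u] <- spare[u] - dm; spare[v] <- spare[v] - dm
          have <- have + 1L
        }
      }
      if (have < lbk) return(NULL)
    }
  }
  fr <- vector("list", sk$n)
  for (i in seq_len(sk$n)) {
    cand <- fringe_candidates(spec, info, i <= sk$p, i, alpha[i], spare[i],
                              mandatory = sk$deg[i] <= 1L)
    if (!length(cand)) return(NULL)
    cd <- cand[sample.int(length(cand), 1L)]
    fr[i] <- list(if (info[[cd]]$nv_ex > 0L) info[[cd]]$template else NULL)
  }
  tryCatch(assemble_graph(sk$n, sk$edges, alpha, beta, fr, tab),
           error = function(e) NULL)
}

#' Enumerate the full extension set of a small specification
#'
#' Exhaustive recursion over the construction rules: every subdivision,
#' leaf-path placement, element assignment, bond assignment and fringe-tree
#' assignment admitted by the bounds.  Intended for specifications whose
#' extension set is small (the brute-force oracle behind the solver tests);
#' enumeration stops with an error if \code{limit} graphs are exceeded.
#'
#' @param spec a \code{\link{target_spec}}.
#' @param limit hard cap on the number of (labeled) candidates assembled.
#' @param dedup drop isomorphic duplicates (by canonical certificate).
#' @return list of \code{\link{chem_graph}} objects.
#' @export
enumerate_extensions <- function(spec, limit = 50000L, dedup = TRUE) {
  info <- spec_fringe_info(spec)
  it <- spec$interior; ch <- spec$chem; seed <- spec$seed; tab <- spec$table
  m <- nrow(seed$edges); p <- seed$n
  out <- list()
  seen <- character(0)
  emitted <- 0L

  emit <- function(g) {
    emitted <<- emitted + 1L
    if (emitted > limit) stop("enumeration limit exceeded")
    if (dedup) {
      crt <- cg_certificate(g)
      if (crt %in% seen) return()
      seen <<- c(seen, crt)
    }
    out[[length(out) + 1L]] <<- g
  }

  # ---- stage 3: labels on a fixed skeleton --------------------------------
  label_skeleton <- function(sk) {
    nsk <- sk$n
    alpha_opts <- vector("list", nsk)
    for (i in seq_len(nsk)) {
      allowed <- if (i <= p) intersect(ch$lambda_star[[i]], ch$lambda_int) else ch$lambda_int
      need <- sk$deg[i] + if (sk$deg[i] <= 1L) 1L else 0L
      allowed <- allowed[elem_valence(tab, allowed) >= need]
      if (!length(allowed)) return()
      alpha_opts[[i]] <- allowed
    }
    nse <- nrow(sk$edges)
    rec_alpha <- function(i, alpha) {
      if (i > nsk) { rec_beta(1L, alpha, rep(1L, nse)) ; return() }
      for (a in alpha_opts[[i]]) { alpha[i] <- a; rec_alpha(i + 1L, alpha) }
    }
    rec_beta <- function(r, alpha, beta) {
      if (r > nse) { check_bd_and_fringe(alpha, beta); return() }
      for (b in 1:3) {
        beta[r] <- b
        # valence feasibility with room for mandatory fringes
        u <- sk$edges[r, 1L]; v <- sk$edges[r, 2L]
        bs_u <- sum(beta[seq_len(r)][sk$edges[seq_len(r), 1L] == u | sk$edges[seq_len(r), 2L] == u])
        bs_v <- sum(beta[seq_len(r)][sk$edges[seq_len(r), 1L] == v | sk$edges[seq_len(r), 2L] == v])
        res_u <- if (sk$deg[u] <= 1L) 1L else 0L
        res_v <- if (sk$deg[v] <= 1L) 1L else 0L
        if (bs_u + res_u > elem_valence(tab, alpha[u])) next
        if (bs_v + res_v > elem_valence(tab, alpha[v])) next
        rec_beta(r + 1L, alpha, beta)
      }
    }
    check_bd_and_fringe <- function(alpha, beta) {
      for (k in seq_len(m)) {
        rows <- which(sk$eowner == k)
        if (sum(beta[rows] == 2L) < it$bd2_lb[k] || sum(beta[rows] == 2L) > it$bd2_ub[k]) return()
        if (sum(beta[rows] == 3L) < it$bd3_lb[k] || sum(beta[rows] == 3L) > it$bd3_ub[k]) return()
      }
      bsum <- integer(nsk)
      for (r in seq_len(nse)) {
        bsum[sk$edges[r, 1L]] <- bsum[sk$edges[r, 1L]] + beta[r]
        bsum[sk$edges[r, 2L]] <- bsum[sk$edges[r, 2L]] + beta[r]
      }
      spare <- elem_valence(tab, alpha) - bsum
      if (any(spare < 0L)) return()
      cand <- vector("list", nsk)
      for (i in seq_len(nsk)) {
        cand[[i]] <- fringe_candidates(spec, info, i <= p, i, alpha[i], spare[i],
                                       mandatory = sk$deg[i] <= 1L)
        if (!length(cand[[i]])) return()
      }
      rec_fringe <- function(i, codes) {
        if (i > nsk) { finish(alpha, beta, codes); return() }
        for (cd in cand[[i]]) { codes[i] <- cd; rec_fringe(i + 1L, codes) }
      }
      rec_fringe(1L, character(nsk))
    }
    finish <- function(alpha, beta, codes) {
      fr <- lapply(codes, function(cd) if (info[[cd]]$nv_ex > 0L) info[[cd]]$template else NULL)
      g <- tryCatch(assemble_graph(nsk, sk$edges, alpha, beta, fr, tab),
                    error = function(e) NULL)
      if (is.null(g)) return()
      if (g$n < ch$n_lb || g$n > ch$n_star) return()
      rep <- validate_extension(g, spec)
      if (rep$is_extension) emit(g)
    }
    rec_alpha(1L, character(nsk))
  }

  # ---- stages 1-2: structural choices -------------------------------------
  try_structure <- function(l, leaf_v, leaf_e) {
    sk <- make_skeleton(spec, l, leaf_v, leaf_e)
    if (sk$n < it$n_int_lb || sk$n > it$n_int_ub) return()
    label_skeleton(sk)
  }

  rec_leaf_e <- function(k, l, leaf_v, leaf_e, budget) {
    if (k > m) { try_structure(l, leaf_v, leaf_e); return() }
    nslots <- max(0L, l[k] - 1L)
    slot_rec <- function(s, cur, used) {
      if (s > nslots) {
        cnt <- sum(cur > 0L)
        if (cnt < it$bl_lb[k] || cnt > it$bl_ub[k]) return()
        if (cnt > 0L) {
          if (max(cur) > it$ch_ub[k] || max(cur) < it$ch_lb[k]) return()
        }
        leaf_e[[k]] <- cur
        rec_leaf_e(k + 1L, l, leaf_v, leaf_e, budget - used)
        return()
      }
      for (len in 0:min(it$ch_ub[k], budget - used)) {
        cur[s] <- len
        slot_rec(s + 1L, cur, used + len)
      }
    }
    slot_rec(1L, integer(nslots), 0L)
  }

  rec_leaf_v <- function(v, l, leaf_v, budget) {
    if (v > p) {
      rec_leaf_e(1L, l, leaf_v, rep(list(integer(0)), m), budget)
      return()
    }
    if (it$v_bl_lb[v] == 0L) { leaf_v[v] <- 0L; rec_leaf_v(v + 1L, l, leaf_v, budget) }
    if (it$v_bl_ub[v] >= 1L) {
      for (len in seq_len(min(it$v_ch_ub[v], budget))) {
        if (len < max(1L, it$v_ch_lb[v])) next
        leaf_v[v] <- len
        rec_leaf_v(v + 1L, l, leaf_v, budget - len)
      }
    }
  }

  rec_len <- function(k, l, budget) {
    if (k > m) {
      if (!seed_connected(seed, l) || !side_ok(spec, l)) return()
      rec_leaf_v(1L, l, integer(p), budget)
      return()
    }
    lo <- it$l_lb[k]; hi <- min(it$l_ub[k], lo + budget + 1L)
    if (lo > hi) return()
    for (lk in seq(lo, hi)) {
      extra <- max(0L, lk - 1L)
      if (extra > budget) next
      l[k] <- lk
      rec_len(k + 1L, l, budget - extra)
    }
  }
  rec_len(1L, integer(m), it$n_int_ub - p)
  out
}
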