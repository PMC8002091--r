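# Extension semantics: validation against a target specification, random
# sampling of extensions, and exhaustive enumeration at toy scale.
#
# A chemical graph G is a (sigma_int, sigma_ce)-extension of the seed graph
# when its interior (at the spec's rho) can be produced from the seed by the
# construction rules -- subdivide each edge within its length bounds, attach
# leaf paths at seed vertices or internal path vertices -- and all interior
# and chemical bounds hold.

# per-code fringe template summaries used across the module
spec_fringe_info <- function(spec) {
  codes <- spec$chem$f_star
  info <- vector("list", length(codes))
  names(info) <- codes
  for (cd in codes) {
    t <- parse_fringe_code(cd)
    info[[cd]] <- c(list(template = t), ft_summary(t, spec$table))
  }
  info
}

# ---------------------------------------------------------------------------
# skeleton: the unlabeled interior produced by one set of structural choices
# ---------------------------------------------------------------------------

# l: path length per seed edge (e01: 0 or 1; eq1: 1)
# leaf_v: leaf-path length per seed vertex (0 = no leaf path)
# leaf_e: list per seed edge: integer vector of length l[e]-1, the leaf-path
#         length hanging at each internal slot (0 = none)
make_skeleton <- function(spec, l, leaf_v, leaf_e) {
  seed <- spec$seed
  p <- seed$n
  role <- rep("seed", p)
  owner <- rep(NA_integer_, p)
  edges <- matrix(integer(0), ncol = 2L)
  eowner <- integer(0)           # seed edge id, or 0 for leaf-path edges
  nv <- p
  anchors <- integer(0)          # vertex at which each pending leaf path hangs
  lengths <- integer(0)
  anchor_edge <- integer(0)      # seed edge owning the anchor slot (0 = seed vertex)
  for (k in seq_len(nrow(seed$edges))) {
    u <- seed$edges[k, 1L]; v <- seed$edges[k, 2L]
    if (l[k] == 0L) next                      # dropped e01 edge
    if (l[k] == 1L) {
      edges <- rbind(edges, c(u, v)); eowner <- c(eowner, k)
    } else {
      prev <- u
      for (s in seq_len(l[k] - 1L)) {
        nv <- nv + 1L
        role <- c(role, "path"); owner <- c(owner, k)
        edges <- rbind(edges, c(prev, nv)); eowner <- c(eowner, k)
        lf <- leaf_e[[k]][s]
        if (lf > 0L) {
          anchors <- c(anchors, nv); lengths <- c(lengths, lf)
          anchor_edge <- c(anchor_edge, k)
        }
        prev <- nv
      }
      edges <- rbind(edges, c(prev, v)); eowner <- c(eowner, k)
    }
  }
  for (v in seq_len(p)) {
    if (leaf_v[v] > 0L) {
      anchors <- c(anchors, v); lengths <- c(lengths, leaf_v[v])
      anchor_edge <- c(anchor_edge, 0L)
    }
  }
  for (j in seq_along(anchors)) {
    prev <- anchors[j]
    for (s in seq_len(lengths[j])) {
      nv <- nv + 1L
      role <- c(role, "leaf"); owner <- c(owner, anchor_edge[j])
      edges <- rbind(edges, c(prev, nv)); eowner <- c(eowner, 0L)
      prev <- nv
    }
  }
  deg <- tabulate(as.integer(edges), nv)
  list(n = nv, p = p, edges = edges, eowner = eowner, role = role,
       owner = owner, deg = deg, l = l, leaf_v = leaf_v, leaf_e = leaf_e)
}

# does dropping the chosen e01 edges keep the seed connected?
seed_connected <- function(seed, l) {
  keep <- which(l > 0L)
  if (seed$n == 1L) return(TRUE)
  ig <- igraph::make_empty_graph(n = seed$n, directed = FALSE)
  if (length(keep)) {
    ig <- igraph::add_edges(ig, as.integer(t(seed$edges[keep, , drop = FALSE])))
  }
  igraph::components(ig)$no == 1L
}

side_ok <- function(spec, l) {
  for (s in spec$side) {
    idx <- match(names(s$coef), spec$seed$edge_names)
    val <- sum(s$coef * l[idx])
    ok <- switch(s$op, "<=" = val <= s$rhs, ">=" = val >= s$rhs, "==" = val == s$rhs,
                 stop("unsupported side-constraint operator ", s$op))
    if (!ok) return(FALSE)
  }
  TRUE
}

# ---------------------------------------------------------------------------
# validation
# ---------------------------------------------------------------------------

#' Validate a chemical graph against a target specification
#'
#' Decomposes the graph at the specification's branch-parameter, searches for
#' a witness mapping its interior back onto the seed graph (inverting the
#' reduction steps: fringe-tree removal, leaf-path removal, path contraction),
#' and checks every interior and chemical bound.  All failures are reported;
#' nothing throws.
#'
#' @param g a \code{\link{chem_graph}}.
#' @param spec a \code{\link{target_spec}}.
#' @return list of class \code{"validation_report"} with \code{is_extension}
#'   (logical) and \code{violations} (list of \code{rule}, \code{location},
#'   \code{observed}, \code{bound}).
#' @export
validate_extension <- function(g, spec) {
  viol <- list()
  add <- function(rule, location, observed, bound) {
    viol[[length(viol) + 1L]] <<- list(rule = rule, location = location,
                                       observed = observed, bound = bound)
  }
  dec <- tryCatch(two_layer(g, spec$rho), moldesign_empty_interior = function(e) NULL)
  if (is.null(dec)) {
    add("interior_structure", "graph", "empty interior", "nonempty interior")
    return(structure(list(is_extension = FALSE, violations = viol),
                     class = "validation_report"))
  }
  int <- dec$interior_vertices
  ch <- spec$chem; it <- spec$interior
  if (g$n < ch$n_lb || g$n > ch$n_star) add("n", "graph", g$n, c(ch$n_lb, ch$n_star))
  if (length(int) < it$n_int_lb || length(int) > it$n_int_ub) {
    add("n_int", "graph", length(int), c(it$n_int_lb, it$n_int_ub))
  }
  bad_elem <- setdiff(unique(g$alpha[int]), ch$lambda_int)
  if (length(bad_elem)) add("lambda_int", "interior", bad_elem, ch$lambda_int)
  cs <- chemical_symbol(g)
  bad_sym <- setdiff(unique(cs[int]), ch$lambda_dg_int)
  if (length(bad_sym)) add("lambda_dg_int", "interior", bad_sym, ch$lambda_dg_int)
  ecs <- if (length(dec$interior_edges)) edge_config(g, dec$interior_edges, dec) else character(0)
  bad_ec <- setdiff(unique(ecs), ch$gamma_int)
  if (length(bad_ec)) add("gamma_int", "interior edges", bad_ec, ch$gamma_int)
  codes <- vapply(dec$fringe_trees, canonical_code, character(1))
  names(codes) <- as.character(int)
  bad_fc <- setdiff(unique(codes), ch$f_star)
  if (length(bad_fc)) add("fringe_set", "fringe trees", bad_fc, "F*")
  # count bounds
  check_counts <- function(counts, lb, ub, rule) {
    for (key in names(lb)) {
      v <- if (key %in% names(counts)) counts[[key]] else 0
      if (v < lb[[key]] || v > ub[[key]]) {
        add(sprintf("%s(%s)", rule, key), "graph", v, c(lb[[key]], ub[[key]]))
      }
    }
  }
  na_all <- table(g$alpha)
  check_counts(as.list(na_all), as.list(ch$na_lb), as.list(ch$na_ub), "na")
  na_int <- table(g$alpha[int])
  check_counts(as.list(na_int), as.list(ch$na_int_lb), as.list(ch$na_int_ub), "na_int")
  ns_int <- table(cs[int])
  check_counts(as.list(ns_int), as.list(ch$ns_int_lb), as.list(ch$ns_int_ub), "ns_int")
  if (length(ecs)) {
    ac <- table(ec_to_ac(ecs, spec$table))
    ec <- table(ecs)
  } else { ac <- ec <- integer(0) }
  check_counts(as.list(ac), as.list(ch$ac_int_lb), as.list(ch$ac_int_ub), "ac_int")
  check_counts(as.list(ec), as.list(ch$ec_int_lb), as.list(ch$ec_int_ub), "ec_int")
  if (!length(viol) || all(vapply(viol, function(v) !grepl("fringe_set|lambda", v$rule), logical(1)))) {
    w <- find_witness(g, dec, spec, codes)
    if (is.null(w)) {
      add("interior_structure", "interior",
          "no seed-graph witness under the interior specification", "witness")
    }
  }
  structure(list(is_extension = length(viol) == 0L, violations = viol),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$is_extension) cat("valid (sigma_int, sigma_ce)-extension\n")
  else {
    cat("not an extension;", length(x$violations), "violation(s):\n")
    for (v in x$violations) {
      cat(sprintf("  %s at %s: observed %s, bound %s\n", v$rule,
                  paste(v$location, collapse = ","),
                  paste(v$observed, collapse = ","),
                  paste(v$bound, collapse = "..")))
    }
  }
  invisible(x)
}

# enumerate simple paths from `from` to `to` in the interior subgraph with
# length (edge count) in [lo, hi], internal vertices outside `blocked`,
# edges outside `used_e`; returns list of list(verts, erows)
interior_paths <- function(adj, from, to, lo, hi, blocked, used_e, cap = 20000L) {
  out <- list()
  path <- integer(hi + 1L); path[1L] <- from
  erows <- integer(hi)
  rec <- function(v, depth) {
    if (length(out) >= cap) return()
    nb <- adj[[v]]
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1L]; e <- nb[r, 2L]
      if (used_e[e]) next
      if (depth + 1L > hi) next
      if (w == to) {
        if (depth + 1L >= lo) {
          erows[depth + 1L] <<- e
          out[[length(out) + 1L]] <<- list(verts = c(path[seq_len(depth + 1L)], to),
                                           erows = erows[seq_len(depth + 1L)])
        }
        next
      }
      if (blocked[w] || w %in% path[seq_len(depth + 1L)]) next
      path[depth + 2L] <<- w
      erows[depth + 1L] <<- e
      used_e[e] <<- TRUE
      rec(w, depth + 1L)
      used_e[e] <<- FALSE
    }
  }
  if (hi >= 1L) rec(from, 0L)
  out
}

# witness search: a mapping of the seed graph into the interior plus a
# consistent path / leaf-path decomposition satisfying sigma_int
find_witness <- function(g, dec, spec, codes) {
  seed <- spec$seed; it <- spec$interior; ch <- spec$chem
  int <- dec$interior_vertices
  q <- length(int)
  p <- seed$n
  if (q < p) return(NULL)
  # interior subgraph with local ids 1..q
  loc <- match(seq_len(g$n), int)       # NA for exterior
  iedges <- matrix(loc[g$edges[dec$interior_edges, , drop = FALSE]], ncol = 2L)
  ne <- nrow(iedges)
  adj <- vector("list", q)
  for (i in seq_len(q)) adj[[i]] <- cbind(integer(0), integer(0))
  for (k in seq_len(ne)) {
    u <- iedges[k, 1L]; v <- iedges[k, 2L]
    adj[[u]] <- rbind(adj[[u]], c(v, k))
    adj[[v]] <- rbind(adj[[v]], c(u, k))
  }
  lcodes <- codes[as.character(int)]
  lalpha <- g$alpha[int]
  # candidate images per seed vertex
  cand <- vector("list", p)
  for (v in seq_len(p)) {
    cand[[v]] <- which(lalpha %in% ch$lambda_star[[v]] &
                       lcodes %in% ch$fringe_v[[v]])
    if (!length(cand[[v]])) return(NULL)
  }
  must_image <- which(!(lcodes %in% ch$fringe_e))
  ebeta <- g$beta[dec$interior_edges]
  edge_order <- order(match(seed$classes, c("eq1", "e01", "ge1", "ge2")))
  found <- NULL

  check_leftover <- function(phi, used_e, path_internal, lengths) {
    covered <- logical(q); covered[phi] <- TRUE; covered[path_internal] <- TRUE
    leftover <- which(!covered)
    # every uncovered edge must connect leftover vertices or attach a leaf path
    leaf_at_vertex <- integer(p)      # leaf-path length at each seed vertex
    leaf_on_edge <- vector("list", nrow(seed$edges))
    for (k in seq_along(leaf_on_edge)) leaf_on_edge[[k]] <- integer(0)
    if (length(must_image) && !all(must_image %in% phi)) return(FALSE)
    rem <- which(!used_e)
    if (length(leftover)) {
      # walk each leaf path from its attachment
      attach <- list()
      for (k in rem) {
        u <- iedges[k, 1L]; v <- iedges[k, 2L]
        cu <- covered[u]; cv <- covered[v]
        if (cu && cv) return(FALSE)            # stray edge between covered vertices
        if (cu || cv) attach[[length(attach) + 1L]] <- if (cu) c(u, v, k) else c(v, u, k)
      }
      visited <- logical(q)
      for (at in attach) {
        anchor <- at[1L]; start <- at[2L]
        if (visited[start]) return(FALSE)      # two attachments into one component
        # walk the path
        len <- 1L; prev <- anchor; cur <- start; visited[cur] <- TRUE
        repeat {
          nb <- adj[[cur]]
          nxt <- nb[!covered[nb[, 1L]] & nb[, 1L] != prev, , drop = FALSE]
          if (nrow(nxt) == 0L) break
          if (nrow(nxt) > 1L) return(FALSE)    # branches: not a path
          prev <- cur; cur <- nxt[1L, 1L]
          if (visited[cur]) return(FALSE)
          visited[cur] <- TRUE
          len <- len + 1L
        }
        # classify the anchor
        sv <- match(anchor, phi)
        if (!is.na(sv)) {
          if (leaf_at_vertex[sv] > 0L) return(FALSE)   # one leaf path per vertex
          if (it$v_bl_ub[sv] < 1L) return(FALSE)
          if (len < max(1L, it$v_ch_lb[sv]) || len > it$v_ch_ub[sv]) return(FALSE)
          leaf_at_vertex[sv] <- len
        } else {
          ke <- path_owner[anchor]
          if (is.na(ke) || ke == 0L) return(FALSE)     # anchored on a leaf path
          leaf_on_edge[[ke]] <- c(leaf_on_edge[[ke]], len)
        }
      }
      if (!all(visited[leftover])) return(FALSE)       # disconnected leftovers
    } else {
      if (any(!used_e)) return(FALSE)
    }
    # leaf path count/length bounds per seed edge and vertex
    for (k in seq_len(nrow(seed$edges))) {
      cnt <- length(leaf_on_edge[[k]])
      if (cnt < it$bl_lb[k] || cnt > it$bl_ub[k]) return(FALSE)
      if (cnt > 0L) {
        if (max(leaf_on_edge[[k]]) > it$ch_ub[k]) return(FALSE)
        if (max(leaf_on_edge[[k]]) < it$ch_lb[k]) return(FALSE)
      }
    }
    for (v in seq_len(p)) {
      if (leaf_at_vertex[v] == 0L && it$v_bl_lb[v] >= 1L) return(FALSE)
    }
    TRUE
  }

  path_owner <- rep(NA_integer_, q)   # seed edge owning each path-internal vertex

  match_edges <- function(ei, phi, used_e, path_internal, lengths, bd2, bd3) {
    if (!is.null(found)) return()
    if (ei > length(edge_order)) {
      if (any(bd2 < it$bd2_lb | bd2 > it$bd2_ub)) return()
      if (any(bd3 < it$bd3_lb | bd3 > it$bd3_ub)) return()
      if (!side_ok(spec, lengths)) return()
      if (check_leftover(phi, used_e, path_internal, lengths)) {
        found <<- list(phi = int[phi], lengths = lengths)
      }
      return()
    }
    k <- edge_order[ei]
    u <- phi[seed$edges[k, 1L]]; v <- phi[seed$edges[k, 2L]]
    cls <- seed$classes[k]
    blocked <- logical(q); blocked[phi] <- TRUE; blocked[path_internal] <- TRUE
    if (cls == "e01" && it$l_lb[k] == 0L) {
      lengths[k] <- 0L
      match_edges(ei + 1L, phi, used_e, path_internal, lengths, bd2, bd3)
      if (!is.null(found)) return()
    }
    lo <- max(it$l_lb[k], if (cls == "ge2") 2L else 1L)
    hi <- min(it$l_ub[k], if (cls %in% c("eq1", "e01")) 1L else q)
    if (lo > hi) return()
    paths <- interior_paths(adj, u, v, lo, hi, blocked, used_e)
    for (pt in paths) {
      internal <- pt$verts[-c(1L, length(pt$verts))]
      used_e2 <- used_e; used_e2[pt$erows] <- TRUE
      po_old <- path_owner[internal]
      path_owner[internal] <<- k
      b <- ebeta[pt$erows]
      bd2k <- bd2; bd2k[k] <- sum(b == 2L)
      bd3k <- bd3; bd3k[k] <- sum(b == 3L)
      lens <- lengths; lens[k] <- length(pt$erows)
      match_edges(ei + 1L, phi, used_e2, c(path_internal, internal), lens, bd2k, bd3k)
      path_owner[internal] <<- po_old
      if (!is.null(found)) return()
    }
  }

  assign_vertex <- function(v, phi) {
    if (!is.null(found)) return()
    if (v > p) {
      match_edges(1L, phi, logical(ne), integer(0),
                  integer(nrow(seed$edges)), integer(nrow(seed$edges)),
                  integer(nrow(seed$edges)))
      return()
    }
    for (w in cand[[v]]) {
      if (w %in% phi[seq_len(v - 1L)]) next
      phi[v] <- w
      assign_vertex(v + 1L, phi)
      if (!is.null(found)) return()
    }
  }
  assign_vertex(1L, integer(p))
  found
}

#' Subdivision test against a seed graph
#'
#' Checks whether a graph \code{s} (with the seed vertices embedded as its
#' first \code{seed$n} vertices) is a subdivision of the seed graph: each
#' \code{ge2} edge replaced by a path of length at least 2, each \code{ge1}
#' edge by a path of length at least 1, each \code{e01} edge kept or dropped,
#' each \code{eq1} edge kept, the paths internally disjoint and covering
#' \code{s} exactly.
#'
#' @param s a \code{\link{chem_graph}} (labels are ignored).
#' @param seed a \code{\link{seed_graph}}.
#' @return \code{list(ok = TRUE, paths = ...)} with the edge-to-path
#'   correspondence, or \code{list(ok = FALSE, rule = ..., edge = ...)}
#'   naming a violated rule.
#' @export
is_subdivision <- function(s, seed) {
  res <- subdivision_search(s, seed, relax = 0L)
  if (!is.null(res)) return(list(ok = TRUE, paths = res))
  # identify a culprit edge: relaxing which class constraint makes it work?
  for (k in seq_len(nrow(seed$edges))) {
    if (seed$classes[k] %in% c("ge2", "eq1")) {
      if (!is.null(subdivision_search(s, seed, relax = k))) {
        return(list(ok = FALSE, rule = paste0("class_", seed$classes[k]),
                    edge = seed$edge_names[k]))
      }
    }
  }
  list(ok = FALSE, rule = "no_subdivision", edge = NA_character_)
}

# exhaustive search for a subdivision correspondence; identity embedding of
# the seed vertices; relax > 0 loosens that edge's class to length >= 1
subdivision_search <- function(s, seed, relax = 0L) {
  p <- seed$n
  if (s$n < p) return(NULL)
  q <- s$n
  ne <- nrow(s$edges)
  adj <- cg_adjacency(s)
  found <- NULL
  rec <- function(ei, used_e, used_v, paths) {
    if (!is.null(found)) return()
    if (ei > nrow(seed$edges)) {
      if (all(used_e) && all(used_v | seq_len(q) <= p)) found <<- paths
      return()
    }
    u <- seed$edges[ei, 1L]; v <- seed$edges[ei, 2L]
    cls <- seed$classes[ei]
    if (cls == "e01") {
      rec(ei + 1L, used_e, used_v, c(paths, list(NULL)))
      if (!is.null(found)) return()
    }
    lo <- if (cls == "ge2" && relax != ei) 2L else 1L
    hi <- if (cls %in% c("eq1", "e01") && relax != ei) 1L else q
    blocked <- logical(q); blocked[seq_len(p)] <- TRUE; blocked[used_v] <- TRUE
    pts <- interior_paths(adj, u, v, lo, hi, blocked, used_e)
    for (pt in pts) {
      internal <- pt$verts[-c(1L, length(pt$verts))]
      ue <- used_e; ue[pt$erows] <- TRUE
      uv <- used_v; uv[internal] <- TRUE
      rec(ei + 1L, ue, uv, c(paths, list(pt$verts)))
      if (!is.null(found)) return()
    }
  }
  rec(1L, logical(ne), logical(q), list())
  if (is.null(found)) NULL else stats::setNames(found, seed$edge_names)
}
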