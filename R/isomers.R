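# Stage 5: counting and enumerating chemical isomers of an inferred graph --
# specification-conforming graphs with exactly the same feature vector.
#
# The interior skeleton (vertices and edges of the interior subgraph) is kept
# fixed; the choice sites are the element labels and bond multiplicities of
# the interior and the fringe-code assignment of each interior vertex.
# Interior rewirings are out of scope.

# skeleton of g under spec's rho, with local interior indexing
isomer_skeleton <- function(g, spec) {
  dec <- two_layer(g, spec$rho)
  int <- dec$interior_vertices
  loc <- match(seq_len(g$n), int)
  edges <- matrix(loc[g$edges[dec$interior_edges, , drop = FALSE]], ncol = 2L)
  codes <- vapply(dec$fringe_trees, canonical_code, character(1))
  list(q = length(int), edges = edges,
       beta = g$beta[dec$interior_edges],
       alpha = g$alpha[int],
       codes = codes,
       deg = tabulate(as.integer(edges), length(int)))
}

# number of automorphisms of the labeled interior (elements + bonds)
interior_automorphisms <- function(sk, spec) {
  tab <- spec$table
  n <- sk$q; ne <- nrow(sk$edges)
  col <- match(sk$alpha, tab$symbol)
  h <- igraph::make_empty_graph(n = n + ne, directed = FALSE)
  if (ne) {
    eadd <- integer(0)
    for (k in seq_len(ne)) {
      eadd <- c(eadd, sk$edges[k, 1L], n + k, n + k, sk$edges[k, 2L])
    }
    h <- igraph::add_edges(h, eadd)
    col <- c(col, nrow(tab) + sk$beta)
  }
  as.numeric(igraph::count_automorphisms(h, colors = col)$group_size)
}

#' Lower bound on the number of chemical isomers
#'
#' Counts, without materializing graphs, the assignments reachable by
#' permuting fringe codes among interchangeable interior vertices -- sites
#' sharing element, interior degree, interior bond sum and candidate set,
#' restricted to codes of equal root degree and root bond sum, so that every
#' permutation preserves the feature vector slot by slot and specification
#' conformance.  Dividing by the automorphism count of the labeled interior
#' and rounding up gives a valid lower bound on the number of isomorphism
#' classes (each class meets at most \code{|Aut|} assignments).
#'
#' @param g_dagger a spec-conforming \code{\link{chem_graph}} (e.g. from
#'   \code{\link{solve_inverse}}).
#' @param spec the \code{\link{target_spec}}.
#' @return integer-valued numeric, at least 1 and at most the exact isomer
#'   count.
#' @export
count_lower_bound <- function(g_dagger, spec) {
  rep <- validate_extension(g_dagger, spec)
  if (!rep$is_extension) stop("g_dagger does not satisfy the specification")
  sk <- isomer_skeleton(g_dagger, spec)
  info <- spec_fringe_info(spec)
  bsum <- integer(sk$q)
  for (k in seq_len(nrow(sk$edges))) {
    bsum[sk$edges[k, 1L]] <- bsum[sk$edges[k, 1L]] + sk$beta[k]
    bsum[sk$edges[k, 2L]] <- bsum[sk$edges[k, 2L]] + sk$beta[k]
  }
  # site class: everything that must agree for codes to be freely permutable
  site_key <- vapply(seq_len(sk$q), function(i) {
    s <- info[[sk$codes[i]]]
    paste(sk$alpha[i], sk$deg[i], bsum[i], s$root_deg, s$root_beta, sep = "|")
  }, character(1))
  N <- 1
  for (key in unique(site_key)) {
    sites <- which(site_key == key)
    counts <- table(sk$codes[sites])
    # distinct arrangements of this multiset over the sites
    N <- N * exp(lgamma(length(sites) + 1) - sum(lgamma(counts + 1)))
  }
  aut <- interior_automorphisms(sk, spec)
  max(1, ceiling(round(N) / aut))
}

#' Enumerate chemical isomers of an inferred graph
#'
#' Backtracking over interior element labels, interior bond multiplicities
#' and fringe-code assignments on the fixed interior skeleton, pruned by the
#' element, fringe and bond count multisets of the reference graph; every
#' complete assignment is kept when its feature vector equals the reference
#' feature vector exactly and it validates against the specification.
#' Results are deduplicated by canonical certificate and returned in
#' certificate order; enumeration stops after \code{limit} distinct isomers.
#'
#' @param g_dagger a spec-conforming \code{\link{chem_graph}}.
#' @param spec the \code{\link{target_spec}}.
#' @param space a \code{\link{descriptor_space}} in which both the reference
#'   and the candidates are featurized.
#' @param limit maximum number of isomers to emit (the count is still a lower
#'   bound when the cap is hit).
#' @param include_reference keep \code{g_dagger} itself in the output list.
#' @return object of class \code{"isomer_enumeration"} with fields
#'   \code{graphs}, \code{lower_bound} and \code{exhausted}.
#' @export
enumerate_isomers <- function(g_dagger, spec, space, limit = 100L,
                              include_reference = TRUE) {
  rep <- validate_extension(g_dagger, spec)
  if (!rep$is_extension) stop("g_dagger does not satisfy the specification")
  target_fv <- feature_vector(g_dagger, space)
  sk <- isomer_skeleton(g_dagger, spec)
  info <- spec_fringe_info(spec)
  tab <- spec$table
  ch <- spec$chem
  q <- sk$q; ne <- nrow(sk$edges)
  na_target <- table(factor(sk$alpha, levels = ch$lambda_int))
  fc_target <- table(sk$codes)
  bd_target <- table(factor(sk$beta, levels = 1:3))
  # per-site candidate codes: anything in F* rooted at the right element
  all_codes <- names(fc_target)
  cand_codes <- lapply(ch$lambda_int, function(a) {
    all_codes[vapply(all_codes, function(cd) info[[cd]]$root_elem == a, logical(1))]
  })
  names(cand_codes) <- ch$lambda_int
  ref_cert <- cg_certificate(g_dagger)
  seen <- character(0)
  graphs <- list()
  hit_cap <- FALSE
  emit <- function(g) {
    crt <- cg_certificate(g)
    if (crt %in% seen) return(TRUE)
    seen <<- c(seen, crt)
    graphs[[length(graphs) + 1L]] <<- g
    if (length(graphs) >= limit) { hit_cap <<- TRUE; return(FALSE) }
    TRUE
  }
  # order: assign alpha+code per vertex, then bonds per edge
  assign_bonds <- function(r, beta, alpha, codes, bd_left) {
    if (hit_cap) return()
    if (r > ne) {
      fr <- lapply(codes, function(cd) if (info[[cd]]$nv_ex > 0L) info[[cd]]$template else NULL)
      g <- tryCatch(assemble_graph(q, sk$edges, alpha, beta, fr, tab),
                    error = function(e) NULL)
      if (is.null(g)) return()
      fv <- tryCatch(feature_vector(g, space), error = function(e) NULL)
      if (is.null(fv) || any(abs(fv - target_fv) > 1e-9)) return()
      if (!validate_extension(g, spec)$is_extension) return()
      emit(g)
      return()
    }
    for (b in 1:3) {
      if (bd_left[b] == 0L) next
      # valence feasibility at both endpoints given fringe root bonds
      beta[r] <- b
      u <- sk$edges[r, 1L]; v <- sk$edges[r, 2L]
      ok <- TRUE
      for (w in c(u, v)) {
        rows <- which((sk$edges[, 1L] == w | sk$edges[, 2L] == w) & seq_len(ne) <= r)
        bs <- sum(beta[rows]) + (sk$deg[w] - length(rows))   # unassigned edges count 1
        if (bs + info[[codes[w]]]$root_beta > elem_valence(tab, alpha[w])) { ok <- FALSE; break }
      }
      if (!ok) next
      bd_left[b] <- bd_left[b] - 1L
      assign_bonds(r + 1L, beta, alpha, codes, bd_left)
      bd_left[b] <- bd_left[b] + 1L
      if (hit_cap) return()
    }
  }
  assign_sites <- function(i, alpha, codes, na_left, fc_left) {
    if (hit_cap) return()
    if (i > q) {
      assign_bonds(1L, integer(ne), alpha, codes, as.integer(bd_target))
      return()
    }
    for (a in ch$lambda_int) {
      if (na_left[[a]] == 0L) next
      if (elem_valence(tab, a) < sk$deg[i]) next
      for (cd in cand_codes[[a]]) {
        if (fc_left[[cd]] == 0L) next
        if (sk$deg[i] <= 1L && info[[cd]]$height != spec$rho) next
        alpha[i] <- a; codes[i] <- cd
        na_left[[a]] <- na_left[[a]] - 1L
        fc_left[[cd]] <- fc_left[[cd]] - 1L
        assign_sites(i + 1L, alpha, codes, na_left, fc_left)
        na_left[[a]] <- na_left[[a]] + 1L
        fc_left[[cd]] <- fc_left[[cd]] + 1L
        if (hit_cap) return()
      }
    }
  }
  assign_sites(1L, character(q), character(q),
               as.list(na_target), as.list(fc_target))
  # deterministic output order by certificate
  ord <- order(seen, method = "radix")
  graphs <- graphs[ord]; seen_sorted <- seen[ord]
  if (!include_reference) {
    keep <- seen_sorted != ref_cert
    graphs <- graphs[keep]
  }
  lb <- if (!hit_cap) length(seen) else max(length(seen), count_lower_bound(g_dagger, spec))
  structure(list(graphs = graphs, lower_bound = lb,
                 exhausted = !hit_cap,
                 reference_certificate = ref_cert),
            class = "isomer_enumeration")
}

#' @export
print.isomer_enumeration <- function(x, ...) {
  cat(sprintf("isomer_enumeration: %d graphs emitted, lower bound %g, exhausted: %s\n",
              length(x$graphs), x$lower_bound, x$exhausted))
  invisible(x)
}
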