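# SDF input/output.  Reading is delegated to ChemmineR; the loader applies
# the dataset filter rules (hydrogen suppression, charge and valence screens,
# minimum carbon count) with per-record skip reasons.  Writing emits strict
# V2000 column layout.

#' Read chemical graphs from an SDF/molfile (V2000)
#'
#' Hydrogen atoms are suppressed.  Records are skipped -- never aborting the
#' batch -- when they are malformed, contain a charged atom (atom-block
#' charge code or \code{M  CHG} line), use an element outside the element
#' table or with a different valence, use a bond order above 3, are
#' disconnected after hydrogen removal, or (when \code{filter} is on) have at
#' most \code{min_carbons} carbon atoms.
#'
#' @param path SDF file.
#' @param table an \code{\link{element_table}}.
#' @param filter apply the small-molecule filter.
#' @param min_carbons records with at most this many carbons are dropped when
#'   \code{filter} is \code{TRUE}.
#' @return list with \code{graphs} (named list of \code{\link{chem_graph}})
#'   and \code{skipped} (data frame of record index, name, reason).
#' @export
read_sdf <- function(path, table = default_element_table(), filter = TRUE,
                     min_carbons = 3L) {
  raw <- readLines(path, warn = FALSE)
  ends <- which(trimws(raw) == "$$$$")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  if (!length(ends)) { starts <- 1L; ends <- length(raw) }
  graphs <- list()
  skipped <- data.frame(index = integer(0), name = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  skip <- function(i, name, reason) {
    skipped[nrow(skipped) + 1L, ] <<- list(i, name, reason)
  }
  for (i in seq_along(starts)) {
    rec <- raw[starts[i]:ends[i]]
    name <- trimws(rec[1L])
    if (name == "") name <- sprintf("record_%d", i)
    if (any(grepl("^M  CHG", rec))) { skip(i, name, "charged element"); next }
    sset <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(rec)))),
      error = function(e) NULL)
    if (is.null(sset) || length(sset) != 1L ||
        !isTRUE(suppressWarnings(ChemmineR::validSDF(sset)))) {
      skip(i, name, "malformed record"); next
    }
    sdf <- sset[[1L]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elems <- sub("_.*$", "", rownames(ab))
    if ("C6" %in% colnames(ab) && any(ab[, "C6"] != 0)) {
      skip(i, name, "charged element"); next
    }
    bb <- matrix(as.numeric(bb), ncol = ncol(bb), dimnames = dimnames(bb))
    if (nrow(ab) == 0L) { skip(i, name, "empty record"); next }
    if (any(!is.na(bb[, "C3"]) & bb[, "C3"] > 3)) {
      skip(i, name, "unsupported bond order"); next
    }
    heavy <- which(elems != "H")
    if (!length(heavy)) { skip(i, name, "no non-hydrogen atoms"); next }
    if (!all(elems[heavy] %in% table$symbol)) {
      skip(i, name, paste("unknown element:",
                          paste(setdiff(elems[heavy], table$symbol), collapse = ","))); next
    }
    keep_b <- !is.na(bb[, "C1"]) & elems[bb[, "C1"]] != "H" & elems[bb[, "C2"]] != "H"
    remap <- match(seq_along(elems), heavy)
    edges <- cbind(remap[bb[keep_b, "C1"]], remap[bb[keep_b, "C2"]])
    g <- tryCatch(chem_graph(length(heavy), edges, elems[heavy],
                             as.integer(bb[keep_b, "C3"]), table),
                  error = function(e) conditionMessage(e))
    if (is.character(g)) { skip(i, name, g); next }
    if (filter && sum(g$alpha == "C") <= min_carbons) {
      skip(i, name, sprintf("at most %d carbon atoms", min_carbons)); next
    }
    graphs[[name]] <- g
  }
  list(graphs = graphs, skipped = skipped)
}

#' Write chemical graphs to an SDF file (V2000)
#'
#' Hydrogens stay implicit; a reader adds them back from the valence model
#' (the hydro-degree of each atom).  Coordinates are written as zero (no
#' depiction is attempted).
#'
#' @param graphs a \code{\link{chem_graph}} or list of them.
#' @param path output file.
#' @param names molecule names (defaults to \code{mol_1, ...}).
#' @export
write_sdf <- function(graphs, path, names = NULL) {
  if (inherits(graphs, "chem_graph")) graphs <- list(graphs)
  if (is.null(names)) names <- sprintf("mol_%d", seq_along(graphs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    writeLines(c(names[i], "  moldesign", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       g$n, nrow(g$edges)), con)
    for (v in seq_len(g$n)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         0, 0, 0, g$alpha[v]), con)
    }
    for (k in seq_len(nrow(g$edges))) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                         g$edges[k, 1L], g$edges[k, 2L], g$beta[k]), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
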