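# Overlap of mode residue sets with disorder-annotation ranges supplied as
# local MobiDB-entry-style JSON files.  No network access: entries are
# local files; numbering agreement with the structure (UniProt sequence
# numbering, 1-based inclusive ranges) is asserted, not remapped.

#' Parse disorder-annotation ranges
#'
#' Reads a MobiDB-entry-style JSON document: an object whose keys are
#' annotation names and whose values contain a `regions` list of
#' `[start, end]` pairs (1-based, inclusive).  Annotations without a
#' regions list (e.g. continuous per-residue scores) are skipped with a
#' warning; unknown keys inside an annotation are tolerated.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @return Named list: annotation name -> integer matrix with columns
#'   `start`, `end`.
#' @export
parse_annotation_ranges <- function(source) {
  doc <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  out <- list()
  skipped <- character()
  for (nm in names(doc)) {
    entry <- doc[[nm]]
    regions <- if (is.list(entry) && !is.null(entry$regions)) entry$regions
               else NULL
    if (is.null(regions)) {
      skipped <- c(skipped, nm)
      next
    }
    mat <- do.call(rbind, lapply(regions, function(r) {
      as.integer(unlist(r)[1:2])
    }))
    colnames(mat) <- c("start", "end")
    if (any(mat[, "start"] > mat[, "end"])) {
      stop("inverted range in annotation '", nm, "'", call. = FALSE)
    }
    out[[nm]] <- mat
  }
  if (length(skipped)) {
    warning("skipped annotation(s) without a regions list: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  out
}

#' Overlap fractions of mode residue sets with annotation ranges
#'
#' For each (mode, annotation) pair: the fraction of the mode's residues
#' covered by any of the annotation's ranges.  Residue numbers must share
#' the annotation's sequence numbering.  Modes with zero residues are
#' omitted.
#'
#' @param mode_residues Named list: mode -> integer vector of residue
#'   numbers (typically the survey-pruned sets from
#'   [prune_segments_for_survey()], mapped to sequence numbering).
#' @param ranges Result of [parse_annotation_ranges()].
#' @return Data frame with columns `mode`, `annotation`, `covered`, `n`,
#'   `fraction`.
#' @export
overlap_fractions <- function(mode_residues, ranges) {
  rows <- list()
  for (mode in names(mode_residues)) {
    res <- unique(mode_residues[[mode]])
    if (!length(res)) next
    for (ann in names(ranges)) {
      r <- ranges[[ann]]
      covered <- vapply(res, function(x) {
        any(x >= r[, "start"] & x <= r[, "end"])
      }, logical(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, annotation = ann,
        covered = sum(covered), n = length(res),
        fraction = mean(covered), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mode = character(), annotation = character(),
                      covered = integer(), n = integer(),
                      fraction = numeric()))
  }
  do.call(rbind, rows)
}

#' Write the overlap table as a delimited file
#'
#' @param table Result of [overlap_fractions()].
#' @param path Output path (tab-separated).
#' @return The path, invisibly.
#' @export
write_overlap_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
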