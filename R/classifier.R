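# The six-mode decision tree, run-smoothing, and the aggressive
# segment-pruning rule used for survey statistics.

.BW_MODES <- c("predictive", "unpacked_high_plddt", "near_predictive",
               "pseudostructure", "barbed_wire", "unphysical")
.LOW_MODES <- c("near_predictive", "pseudostructure", "barbed_wire",
                "unphysical")

#' Prediction mode labels
#'
#' @return Character vector of the six mode names in canonical order.
#' @export
mode_labels <- function() .BW_MODES

#' Classifier configuration
#'
#' All numeric thresholds of the pipeline in one place.  Defaults follow
#' the published tool: pLDDT >= 70 is high confidence; packing cutoffs
#' > 0.6 (helix/coil) and > 0.35 (strand); contact gap 0.25 A; covalent
#' outliers at |z| > 4; high-psi band (+60, +170); signature box
#' (-15, +170) x (+60, +170); cis/twisted omega bounds 30/150 degrees;
#' 3-residue density window; 5-residue packing window; smoothing absorbs
#' runs of length <= 2.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `bw_config`.
#' @export
bw_config <- function(...) {
  cfg <- list(
    plddt_high = 70.0,
    pack_cutoff_helix_coil = 0.6,
    pack_cutoff_strand = 0.35,
    contact_gap = 0.25,
    min_seq_sep = 4L,
    bond_z_cutoff = 4.0,
    high_psi_band = c(60, 170),
    signature_box = c(-15, 170, 60, 170),
    cis_max = 30,
    trans_min = 150,
    density_window = 3L,
    packing_window = 5L,
    smoothing_max_run = 2L,
    ca_angle_lo = 73, ca_angle_hi = 155,
    ca_d_lo = 2.7, ca_d_hi = 4.1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  class(cfg) <- "bw_config"
  cfg
}

#' Classify one residue into a prediction mode
#'
#' pLDDT >= 70 (inclusive): packed residues are `predictive`, unpacked are
#' `unpacked_high_plddt`; outlier evidence is ignored at high confidence.
#' Below 70, with `bad` = high outlier density OR signature outlier:
#' packed & !bad -> `near_predictive`; packed & bad -> `unphysical`;
#' unpacked & !bad -> `pseudostructure`; unpacked & bad -> `barbed_wire`.
#'
#' @param plddt,packed,high_density,signature Vectorised inputs.
#' @param cfg A [bw_config()].
#' @return Character vector of mode labels (`NA` where pLDDT is `NA`).
#' @export
classify_residue <- function(plddt, packed, high_density, signature,
                             cfg = bw_config()) {
  m <- max(length(plddt), length(packed), length(high_density),
           length(signature))
  plddt <- rep_len(plddt, m)
  packed <- rep_len(packed, m)
  bad <- rep_len(high_density, m) | rep_len(signature, m)
  out <- rep(NA_character_, m)
  hi <- !is.na(plddt) & plddt >= cfg$plddt_high
  lo <- !is.na(plddt) & !hi
  out[hi & packed] <- "predictive"
  out[hi & !packed] <- "unpacked_high_plddt"
  out[lo & packed & !bad] <- "near_predictive"
  out[lo & packed & bad] <- "unphysical"
  out[lo & !packed & !bad] <- "pseudostructure"
  out[lo & !packed & bad] <- "barbed_wire"
  out
}

#' Smooth isolated mode runs
#'
#' Within each chain segment, a maximal run of 1 or 2 residues whose mode
#' is a low-pLDDT category, flanked on both sides by residues of one
#' identical *other* category, is relabeled to match its surroundings.
#' Passes repeat until a fixed point; runs touching a segment terminus (or
#' an unclassified residue) are never relabeled.
#'
#' @param labels Character vector of per-residue modes (`NA` allowed for
#'   ineligible residues; `NA` breaks runs and acts as a terminus).
#' @param segments Integer segment ids, one per residue.
#' @param max_run Longest run eligible for relabeling (default 2).
#' @return Character vector of smoothed labels.
#' @export
smooth_modes <- function(labels, segments, max_run = 2L) {
  n <- length(labels)
  repeat {
    changed <- FALSE
    i <- 1L
    while (i <= n) {
      if (is.na(labels[i])) { i <- i + 1L; next }
      j <- i
      while (j < n && !is.na(labels[j + 1L]) && labels[j + 1L] == labels[i] &&
             segments[j + 1L] == segments[i]) j <- j + 1L
      len <- j - i + 1L
      if (len <= max_run && labels[i] %in% .LOW_MODES) {
        lf <- if (i > 1L && segments[i - 1L] == segments[i]) labels[i - 1L]
              else NA_character_
        rf <- if (j < n && segments[j + 1L] == segments[i]) labels[j + 1L]
              else NA_character_
        if (!is.na(lf) && !is.na(rf) && lf == rf && lf != labels[i]) {
          labels[i:j] <- lf
          changed <- TRUE
        }
      }
      i <- j + 1L
    }
    if (!changed) break
  }
  labels
}

#' Prune pre-smoothing segments for survey use
#'
#' For every maximal pre-smoothing run of `barbed_wire`, `pseudostructure`
#' or `near_predictive`, drop 3 residues from each end and keep the
#' interior only when at least 3 residues remain.  This focuses survey
#' statistics on unambiguous cases of each mode.
#'
#' @param labels Pre-smoothing per-residue modes.
#' @param segments Integer segment ids.
#' @param modes Modes subject to pruning.
#' @param trim Residues removed from each end of a run.
#' @param min_keep Minimum surviving interior length.
#' @return Named list: mode -> integer vector of surviving residue indices
#'   (modes with no survivors are omitted).
#' @export
prune_segments_for_survey <- function(labels, segments,
                                      modes = c("barbed_wire",
                                                "pseudostructure",
                                                "near_predictive"),
                                      trim = 3L, min_keep = 3L) {
  n <- length(labels)
  out <- stats::setNames(vector("list", length(modes)), modes)
  i <- 1L
  while (i <= n) {
    if (is.na(labels[i])) { i <- i + 1L; next }
    j <- i
    while (j < n && !is.na(labels[j + 1L]) && labels[j + 1L] == labels[i] &&
           segments[j + 1L] == segments[i]) j <- j + 1L
    if (labels[i] %in% modes) {
      lo <- i + trim
      hi <- j - trim
      if (hi - lo + 1L >= min_keep) {
        out[[labels[i]]] <- c(out[[labels[i]]], lo:hi)
      }
    }
    i <- j + 1L
  }
  out[!vapply(out, is.null, logical(1L))]
}
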