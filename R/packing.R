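# Tertiary-contact packing.  Contacts are heavy-atom pairs whose distance
# is at most the sum of van der Waals radii plus a gap (default 0.25 A,
# boundary inclusive), excluding sequence-local pairs (separation <= 4 in
# the same chain) and pairs internal to one secondary-structure element, so
# that helices and sheets must touch *other* parts of the structure to
# count as packed.  This heavy-atom distance criterion replaces the
# hydrogen-inclusive Probe dot-surface analysis of the reference pipeline;
# absolute scores therefore differ from that tool, and the bundled 0.6 /
# 0.35 cutoffs are retained as configurable defaults.

#' Find tertiary steric contacts
#'
#' Uses a uniform-grid cell list (cell edge = largest possible contact
#' distance), so cost is near-linear in atom count; an O(n^2) scan is used
#' as the test oracle.
#'
#' @param model A `bw_model` with segments populated.
#' @param radii Named element-to-radius vector ([default_radii()]).
#' @param ss Result of [assign_secondary_structure()], or `NULL` to skip
#'   the intra-element exclusion.
#' @param gap Van der Waals surface separation cutoff, Angstrom.
#' @param min_seq_sep Pairs at sequence separation <= this (same chain) are
#'   excluded.
#' @return Data frame of unordered atom pairs: `a`, `b` (row indices into
#'   `model$atoms`), `dist`.
#' @export
find_contacts <- function(model, radii = default_radii(), ss = NULL,
                          gap = 0.25, min_seq_sep = 4L) {
  at <- model$atoms
  na <- nrow(at)
  if (na < 2L) return(data.frame(a = integer(), b = integer(), dist = numeric()))
  r <- vdw_radius(at$element, radii)
  res <- model$residues
  # ordinal position within chain (sequence distance is positional, robust
  # to insertion codes and numbering gaps)
  ord <- stats::ave(seq_len(nrow(res)), res$chain, FUN = seq_along)
  elem_id <- if (is.null(ss)) rep(NA_integer_, nrow(res)) else ss$element_id
  ri <- at$res_index
  cutoff <- 2 * max(r) + gap
  cell <- paste(floor(at$x / cutoff), floor(at$y / cutoff),
                floor(at$z / cutoff), sep = ",")
  cells <- split(seq_len(na), cell)
  key <- do.call(rbind, strsplit(names(cells), ",", fixed = TRUE))
  key <- matrix(as.integer(key), ncol = 3L)
  cell_index <- stats::setNames(seq_along(cells), names(cells))
  pa <- pb <- integer(0)
  pd <- numeric(0)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (ci in seq_along(cells)) {
    ai <- cells[[ci]]
    for (oi in seq_len(nrow(offs))) {
      nb_key <- paste(key[ci, 1L] + offs[oi, 1L], key[ci, 2L] + offs[oi, 2L],
                      key[ci, 3L] + offs[oi, 3L], sep = ",")
      cj <- cell_index[nb_key]
      if (is.na(cj) || cj < ci) next
      bj <- cells[[cj]]
      for (a in ai) {
        cand <- if (cj == ci) bj[bj > a] else bj
        if (!length(cand)) next
        d2 <- (xyz[cand, 1L] - xyz[a, 1L])^2 + (xyz[cand, 2L] - xyz[a, 2L])^2 +
          (xyz[cand, 3L] - xyz[a, 3L])^2
        lim <- (r[a] + r[cand] + gap)^2
        hit <- cand[d2 <= lim]
        if (length(hit)) {
          pa <- c(pa, rep.int(a, length(hit)))
          pb <- c(pb, hit)
          pd <- c(pd, sqrt(d2[d2 <= lim]))
        }
      }
    }
  }
  if (!length(pa)) return(data.frame(a = integer(), b = integer(), dist = numeric()))
  ra <- ri[pa]; rb <- ri[pb]
  same_chain <- res$chain[ra] == res$chain[rb]
  seq_sep <- abs(ord[ra] - ord[rb])
  local_pair <- same_chain & seq_sep <= min_seq_sep
  same_elem <- !is.na(elem_id[ra]) & !is.na(elem_id[rb]) &
    elem_id[ra] == elem_id[rb]
  keep <- !local_pair & !same_elem
  out <- data.frame(a = pmin(pa, pb)[keep], b = pmax(pa, pb)[keep],
                    dist = pd[keep])
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-residue packing score and packed verdict
#'
#' For each residue, the score is the number of distinct qualifying contact
#' pairs touching (at least one atom in) the 5-residue window i-2..i+2 of
#' the residue's segment, divided by the heavy-atom count of that window.
#' The verdict uses > `cutoff_strand` for strand residues (whose intra-sheet
#' contacts were excluded) and > `cutoff_other` for helix and coil.
#'
#' @param model A `bw_model`.
#' @param contacts Result of [find_contacts()].
#' @param ss Result of [assign_secondary_structure()] (used for the
#'   per-residue cutoff), or `NULL` for all-coil.
#' @param cutoff_other,cutoff_strand Packed-score cutoffs (strict `>`).
#' @param half_window Residues on each side of i in the window (default 2).
#' @return Data frame per residue: `contact_count`, `window_heavy_atoms`,
#'   `score`, `packed`.
#' @export
packing_score <- function(model, contacts, ss = NULL,
                          cutoff_other = 0.6, cutoff_strand = 0.35,
                          half_window = 2L) {
  res <- model$residues
  n <- nrow(res)
  seg <- res$segment
  atoms_per_res <- tabulate(model$atoms$res_index, nbins = n)
  # residue -> contact-pair ids touching it
  touch <- vector("list", n)
  if (nrow(contacts)) {
    ra <- model$atoms$res_index[contacts$a]
    rb <- model$atoms$res_index[contacts$b]
    for (p in seq_along(ra)) {
      touch[[ra[p]]] <- c(touch[[ra[p]]], p)
      if (rb[p] != ra[p]) touch[[rb[p]]] <- c(touch[[rb[p]]], p)
    }
  }
  count <- heavy <- integer(n)
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- (i - half_window):(i + half_window)
    w <- w[w >= 1L & w <= n]
    w <- w[seg[w] == seg[i]]
    heavy[i] <- sum(atoms_per_res[w])
    count[i] <- length(unique(unlist(touch[w])))
    if (heavy[i] > 0L) score[i] <- count[i] / heavy[i]
  }
  sstype <- if (is.null(ss)) rep("coil", n) else ss$ss
  data.frame(contact_count = count, window_heavy_atoms = heavy,
             score = score,
             packed = is_packed(score, sstype, cutoff_other, cutoff_strand))
}

#' Packed verdict from a packing score
#'
#' @param score Numeric packing score(s).
#' @param ss `"helix"`, `"strand"` or `"coil"` (recycled).
#' @param cutoff_other,cutoff_strand Cutoffs; strict `>` comparisons.
#' @return Logical vector (`FALSE` for `NA` scores).
#' @export
is_packed <- function(score, ss, cutoff_other = 0.6, cutoff_strand = 0.35) {
  ss <- rep_len(ss, length(score))
  cut <- ifelse(ss == "strand", cutoff_strand, cutoff_other)
  !is.na(score) & score > cut
}
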