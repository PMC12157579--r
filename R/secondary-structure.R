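# CA-only secondary-structure assignment (P-SEA style).  Must work without
# N/C/O atoms and on distorted low-pLDDT models, which is why no
# hydrogen-bond (DSSP) criteria are used.

#' Assign secondary structure from CA geometry
#'
#' P-SEA-style criteria on the CA trace: a four-CA window starting at i is
#' helix-like when d(CA_i, CA_i+3) lies in `helix_d13` and the virtual
#' dihedral CA_i..CA_i+3 lies in `helix_dih`; a three-CA window is
#' strand-like when d(CA_i, CA_i+2) lies in `strand_d13` and the virtual
#' angle at CA_i+1 lies in `strand_ang`.  A window hit marks only its
#' central residue(s) (middle two for helix, middle one for strand), so a
#' run needs several consecutive window hits; helix wins over strand on
#' conflict; runs shorter than the minimum length (helix 5, strand 3)
#' revert to coil.  Surviving runs get
#' consecutive element ids and never cross segment boundaries.
#'
#' @param model A `bw_model` with segments populated.
#' @param helix_d13,helix_dih,strand_d13,strand_ang Numeric length-2
#'   acceptance windows (Angstrom / degrees).
#' @param min_helix,min_strand Minimum run lengths.
#' @return Data frame with per-residue `ss` (`"helix"`, `"strand"`,
#'   `"coil"`) and `element_id` (integer, `NA` for coil).
#' @export
assign_secondary_structure <- function(model,
                                       helix_d13 = c(4.8, 5.6),
                                       helix_dih = c(40, 70),
                                       strand_d13 = c(6.3, 7.1),
                                       strand_ang = c(110, 150),
                                       min_helix = 5L, min_strand = 3L) {
  res <- model$residues
  n <- nrow(res)
  CA <- atom_coords(model, "CA")
  seg <- res$segment
  helix <- strand <- logical(n)
  in_win <- function(x, w) !is.na(x) && x >= w[1L] && x <= w[2L]
  for (i in seq_len(n)) {
    if (i + 3L <= n && seg[i] == seg[i + 3L] && !anyNA(CA[i:(i + 3L), ])) {
      d <- vnorm(CA[i + 3L, ] - CA[i, ])
      t <- vec_dihedral(CA[i, ], CA[i + 1L, ], CA[i + 2L, ], CA[i + 3L, ])
      if (in_win(d, helix_d13) && in_win(t, helix_dih)) {
        # mark the middle two: isolated hits must corroborate each other
        helix[(i + 1L):(i + 2L)] <- TRUE
      }
    }
    if (i + 2L <= n && seg[i] == seg[i + 2L] && !anyNA(CA[i:(i + 2L), ])) {
      d <- vnorm(CA[i + 2L, ] - CA[i, ])
      a <- vec_angle(CA[i, ], CA[i + 1L, ], CA[i + 2L, ])
      if (in_win(d, strand_d13) && in_win(a, strand_ang)) {
        strand[i + 1L] <- TRUE
      }
    }
  }
  ss <- ifelse(helix, "helix", ifelse(strand, "strand", "coil"))
  # enforce minimum run lengths within segments, then number elements
  element_id <- rep(NA_integer_, n)
  next_id <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ss[j + 1L] == ss[i] && seg[j + 1L] == seg[i]) j <- j + 1L
    len <- j - i + 1L
    if (ss[i] == "helix" && len < min_helix) ss[i:j] <- "coil"
    if (ss[i] == "strand" && len < min_strand) ss[i:j] <- "coil"
    i <- j + 1L
  }
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ss[j + 1L] == ss[i] && seg[j + 1L] == seg[i]) j <- j + 1L
    if (ss[i] != "coil") {
      next_id <- next_id + 1L
      element_id[i:j] <- next_id
    }
    i <- j + 1L
  }
  data.frame(ss = ss, element_id = element_id, stringsAsFactors = FALSE)
}
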