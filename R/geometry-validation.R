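# Backbone validation: dihedrals, peptide-bond classes, covalent-geometry
# z-scores, coarse Ramachandran status, a CA-virtual-geometry proxy for
# CaBLAM, and the derived outlier-density and signature-outlier booleans
# that drive the mode classifier.

#' Compute backbone dihedrals
#'
#' phi(i) from C(i-1),N(i),CA(i),C(i); psi(i) from N(i),CA(i),C(i),N(i+1);
#' omega of the bond (i,i+1) from CA(i),C(i),N(i+1),CA(i+1).  Dihedrals are
#' undefined (`NA`) at segment termini, where atoms are missing, or when a
#' defining quadruple is degenerate (collinear).
#'
#' @param model A `bw_model` with segments populated.
#' @return Data frame with one row per residue: `phi`, `psi`, `omega_prev`,
#'   `omega_next` (degrees) and `degenerate` (any defining quadruple
#'   collinear).
#' @export
compute_backbone_dihedrals <- function(model) {
  res <- model$residues
  n <- nrow(res)
  N <- atom_coords(model, "N")
  CA <- atom_coords(model, "CA")
  C <- atom_coords(model, "C")
  phi <- psi <- om <- rep(NA_real_, n)  # om[i] = omega of bond (i, i+1)
  degen <- logical(n)
  linked <- function(i, j) res$segment[i] == res$segment[j]
  dih <- function(a, b, c, d, ires) {
    if (anyNA(c(a, b, c, d))) return(NA_real_)
    v <- vec_dihedral(a, b, c, d)
    if (is.na(v)) degen[ires] <<- TRUE
    v
  }
  for (i in seq_len(n)) {
    if (i > 1L && linked(i - 1L, i)) {
      phi[i] <- dih(C[i - 1L, ], N[i, ], CA[i, ], C[i, ], i)
    }
    if (i < n && linked(i, i + 1L)) {
      psi[i] <- dih(N[i, ], CA[i, ], C[i, ], N[i + 1L, ], i)
      om[i] <- dih(CA[i, ], C[i, ], N[i + 1L, ], CA[i + 1L, ], i)
    }
  }
  data.frame(
    phi = phi, psi = psi,
    omega_prev = c(NA_real_, om[-n])[seq_len(n)],
    omega_next = om,
    degenerate = degen
  )
}

#' Classify a peptide bond from its omega torsion
#'
#' MolProbity omegalyze convention: |omega| <= 30 is cis (cis-Pro when the
#' following residue is proline, cis-nonPro otherwise), |omega| >= 150 is
#' trans, anything between is twisted.
#'
#' @param omega Omega torsion in degrees (vectorised).
#' @param next_residue_name 3-letter code of the residue on the N side of
#'   the bond (recycled).
#' @param cis_max,trans_min Class boundaries in degrees.
#' @return Character vector in `{"trans","cis_pro","cis_nonpro","twisted"}`.
#' @export
classify_peptide_bond <- function(omega, next_residue_name,
                                  cis_max = 30, trans_min = 150) {
  next_residue_name <- rep_len(toupper(next_residue_name), length(omega))
  out <- rep(NA_character_, length(omega))
  a <- abs(omega)
  out[a >= trans_min] <- "trans"
  cis <- !is.na(a) & a <= cis_max
  out[cis] <- ifelse(next_residue_name[cis] == "PRO", "cis_pro", "cis_nonpro")
  out[!is.na(a) & a > cis_max & a < trans_min] <- "twisted"
  out
}

# Peptide-bond table: one row per intra-segment bond (i, i+1) with omega,
# class, C-N-CA z and its outlier flag.
peptide_bond_table <- function(model, dihedrals, geom,
                               cis_max = 30, trans_min = 150) {
  res <- model$residues
  n <- nrow(res)
  i <- if (n > 1L) which(res$segment[-n] == res$segment[-1L]) else integer()
  if (!length(i)) {
    return(data.frame(i = integer(), j = integer(), omega = numeric(),
                      kind = character(), cnca_z = numeric(),
                      cnca_outlier = logical()))
  }
  omega <- dihedrals$omega_next[i]
  kind <- classify_peptide_bond(omega, res$resname[i + 1L], cis_max, trans_min)
  data.frame(
    i = i, j = i + 1L, omega = omega, kind = kind,
    cnca_z = geom$cnca_z[i + 1L],
    cnca_outlier = geom$cnca_outlier[i + 1L],
    stringsAsFactors = FALSE
  )
}

#' Validate backbone covalent geometry
#'
#' Computes z = (observed - target) / sigma for the backbone bonds N-CA,
#' CA-C, C-O, C-N and angles N-CA-C, CA-C-N, CA-C-O, C-N-CA against the
#' bundled restraint table.  A measure is an outlier when |z| strictly
#' exceeds `z_cutoff` (default 4, the -4 sigma convention).  Measures that
#' span the peptide bond (C-N, CA-C-N, C-N-CA) mark both sharing residues;
#' the C-N-CA angle of the bond into residue i is additionally reported
#' per-bond for the signature-outlier rule.
#'
#' @param model A `bw_model` with segments populated.
#' @param restraints Restraint table ([backbone_restraints()]).
#' @param z_cutoff Outlier threshold on |z| (strict).
#' @return List with `measures` (long data frame: `res`, `measure`,
#'   `observed`, `target`, `sigma`, `z`, `outlier`, `shared_with`),
#'   `covalent_outlier` (per-residue logical), `cnca_z` and `cnca_outlier`
#'   (per-residue, for the bond *into* that residue; NA/FALSE at segment
#'   starts).
#' @export
validate_bond_geometry <- function(model, restraints = backbone_restraints(),
                                   z_cutoff = 4.0) {
  res <- model$residues
  n <- nrow(res)
  N <- atom_coords(model, "N")
  CA <- atom_coords(model, "CA")
  C <- atom_coords(model, "C")
  O <- atom_coords(model, "O")
  rows <- vector("list", 8L * n)
  k <- 0L
  cnca_z <- rep(NA_real_, n)
  add <- function(ri, measure, observed, shared_with = NA_integer_) {
    if (is.na(observed)) return(invisible(NULL))
    r <- restraint_lookup(measure, restraints)
    k <<- k + 1L
    rows[[k]] <<- data.frame(
      res = ri, measure = measure, observed = observed,
      target = r$target, sigma = r$sigma,
      z = (observed - r$target) / r$sigma,
      shared_with = shared_with, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  dst <- function(a, b) if (anyNA(c(a, b))) NA_real_ else vnorm(a - b)
  ang <- function(a, b, c) if (anyNA(c(a, b, c))) NA_real_ else vec_angle(a, b, c)
  for (i in seq_len(n)) {
    add(i, "N-CA", dst(N[i, ], CA[i, ]))
    add(i, "CA-C", dst(CA[i, ], C[i, ]))
    add(i, "C-O", dst(C[i, ], O[i, ]))
    add(i, "N-CA-C", ang(N[i, ], CA[i, ], C[i, ]))
    add(i, "CA-C-O", ang(CA[i, ], C[i, ], O[i, ]))
    if (i < n && res$segment[i] == res$segment[i + 1L]) {
      add(i, "C-N", dst(C[i, ], N[i + 1L, ]), shared_with = i + 1L)
      add(i, "CA-C-N", ang(CA[i, ], C[i, ], N[i + 1L, ]), shared_with = i + 1L)
      cnca <- ang(C[i, ], N[i + 1L, ], CA[i + 1L, ])
      add(i, "C-N-CA", cnca, shared_with = i + 1L)
      if (!is.na(cnca)) {
        r <- restraint_lookup("C-N-CA", restraints)
        cnca_z[i + 1L] <- (cnca - r$target) / r$sigma
      }
    }
  }
  measures <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(res = integer(), measure = character(), observed = numeric(),
               target = numeric(), sigma = numeric(), z = numeric(),
               shared_with = integer())
  # strict > with a small numerical guard: an observation sitting exactly
  # at the cutoff (e.g. the -4 sigma boundary) is not an outlier even when
  # floating-point noise nudges |z| across it
  measures$outlier <- abs(measures$z) > z_cutoff + 1e-6
  covalent <- logical(n)
  out_rows <- measures[measures$outlier, , drop = FALSE]
  covalent[unique(out_rows$res)] <- TRUE
  sw <- out_rows$shared_with[!is.na(out_rows$shared_with)]
  covalent[unique(sw)] <- TRUE
  list(measures = measures, covalent_outlier = covalent,
       cnca_z = cnca_z,
       cnca_outlier = !is.na(cnca_z) & abs(cnca_z) > z_cutoff + 1e-6)
}

# ---------------------------------------------------------------------------
# Ramachandran: bundled coarse region table.  Rectangular favored/allowed
# regions per residue class; points outside every rectangle are outliers.
# This is deliberately coarse -- the contract is that alpha/beta cores are
# favored and the upper-right signature box interior (general class) is an
# outlier -- and externally computed statuses can be injected to override.

rama_regions <- local({
  rect <- function(class, status, p1, p2, s1, s2) {
    data.frame(class = class, status = status,
               phi_lo = p1, phi_hi = p2, psi_lo = s1, psi_hi = s2,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    # general: beta/PPII, alpha, left-handed alpha
    rect("general", "favored", -180, -45, 80, 180),
    rect("general", "favored", -160, -45, -70, -5),
    rect("general", "favored", 30, 100, -20, 55),
    rect("general", "allowed", -180, -30, 50, 180),
    rect("general", "allowed", -180, -30, -110, 50),
    rect("general", "allowed", -180, -45, -180, -150),
    rect("general", "allowed", 20, 110, -40, 60),
    # glycine: achiral, broad mirrored regions; outlier only near phi ~ 0
    rect("glycine", "favored", -180, -45, 100, 180),
    rect("glycine", "favored", 45, 180, -180, -100),
    rect("glycine", "favored", -180, -45, -85, 10),
    rect("glycine", "favored", 45, 180, -10, 85),
    rect("glycine", "allowed", -180, -30, -180, 180),
    rect("glycine", "allowed", 30, 180, -180, 180),
    # proline: phi restricted by the ring
    rect("proline", "favored", -100, -45, 100, 180),
    rect("proline", "favored", -100, -45, -60, 0),
    rect("proline", "allowed", -110, -40, 60, 180),
    rect("proline", "allowed", -110, -40, -75, 30),
    # pre-proline: general minus the left-handed alpha region
    rect("pre_proline", "favored", -180, -45, 80, 180),
    rect("pre_proline", "favored", -160, -45, -70, -5),
    rect("pre_proline", "allowed", -180, -30, 50, 180),
    rect("pre_proline", "allowed", -180, -30, -110, 50)
  )
  function() tab
})

#' Evaluate Ramachandran status and signature-box membership
#'
#' Status comes from the bundled coarse favored/allowed region table for
#' the residue class (pluggable: external per-residue statuses may be
#' injected downstream).  Independently of status, `in_signature_box` tests
#' the open box -15 < phi < +170, +60 < psi < +170 and `in_high_psi_band`
#' tests +60 < psi < +170.
#'
#' @param phi,psi Torsions in degrees (vectorised; `NA` allowed).
#' @param residue_class One of `"general"`, `"glycine"`, `"proline"`,
#'   `"pre_proline"` (recycled).
#' @param box Signature box bounds `c(phi_lo, phi_hi, psi_lo, psi_hi)`.
#' @param band High-psi band bounds `c(lo, hi)`.
#' @return Data frame: `status` (`favored`/`allowed`/`outlier`/
#'   `unevaluable`), `in_signature_box`, `in_high_psi_band`,
#'   `residue_class`.
#' @export
evaluate_ramachandran <- function(phi, psi, residue_class = "general",
                                  box = c(-15, 170, 60, 170),
                                  band = c(60, 170)) {
  m <- max(length(phi), length(psi), length(residue_class))
  phi <- rep_len(phi, m)
  psi <- rep_len(psi, m)
  residue_class <- rep_len(residue_class, m)
  tab <- rama_regions()
  status <- character(m)
  for (i in seq_len(m)) {
    if (is.na(phi[i]) || is.na(psi[i])) {
      status[i] <- "unevaluable"
      next
    }
    rc <- tab[tab$class == residue_class[i], , drop = FALSE]
    hit <- phi[i] >= rc$phi_lo & phi[i] <= rc$phi_hi &
      psi[i] >= rc$psi_lo & psi[i] <= rc$psi_hi
    status[i] <- if (any(hit & rc$status == "favored")) "favored"
      else if (any(hit)) "allowed" else "outlier"
  }
  ok <- !is.na(phi) & !is.na(psi)
  in_box <- ok & phi > box[1L] & phi < box[2L] & psi > box[3L] & psi < box[4L]
  in_band <- ok & psi > band[1L] & psi < band[2L]
  data.frame(status = status, in_signature_box = in_box,
             in_high_psi_band = in_band, residue_class = residue_class,
             stringsAsFactors = FALSE)
}

# residue class per position: proline/glycine by name, pre_proline when the
# next intra-segment residue is PRO, general otherwise
residue_rama_class <- function(model) {
  res <- model$residues
  n <- nrow(res)
  cls <- rep("general", n)
  cls[res$resname == "GLY"] <- "glycine"
  cls[res$resname == "PRO"] <- "proline"
  if (n > 1L) {
    pre <- which(seq_len(n) < n &
                   res$resname[c(2:n, n)] == "PRO" &
                   res$segment == res$segment[c(2:n, n)] &
                   cls == "general")
    cls[pre] <- "pre_proline"
  }
  cls
}

#' Flag CA-virtual-geometry outliers (CaBLAM proxy)
#'
#' A documented stand-in for CaBLAM: residue i is flagged iff the virtual
#' angle CA(i-1)-CA(i)-CA(i+1) is below `angle_lo` or above `angle_hi`, or
#' any adjacent intra-segment CA-CA distance falls outside
#' `[d_lo, d_hi]`.  Residues without both intra-segment neighbours are
#' never flagged.  An injected external outlier list overrides the proxy.
#'
#' @param model A `bw_model`.
#' @param angle_lo,angle_hi Virtual-angle bounds, degrees.
#' @param d_lo,d_hi Adjacent CA-CA distance bounds, Angstrom.
#' @param inject Optional logical vector (or residue uid character vector)
#'   of externally computed CA-geometry outliers; replaces the proxy.
#' @return Logical vector, one element per residue.
#' @export
flag_ca_geometry <- function(model, angle_lo = 73, angle_hi = 155,
                             d_lo = 2.7, d_hi = 4.1, inject = NULL) {
  res <- model$residues
  n <- nrow(res)
  if (!is.null(inject)) {
    if (is.character(inject)) return(res$uid %in% inject)
    return(rep_len(as.logical(inject), n))
  }
  CA <- atom_coords(model, "CA")
  out <- logical(n)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    if (res$segment[i - 1L] != res$segment[i] ||
        res$segment[i] != res$segment[i + 1L]) next
    if (anyNA(CA[(i - 1L):(i + 1L), ])) next
    a <- vec_angle(CA[i - 1L, ], CA[i, ], CA[i + 1L, ])
    d1 <- vnorm(CA[i, ] - CA[i - 1L, ])
    d2 <- vnorm(CA[i + 1L, ] - CA[i, ])
    out[i] <- (!is.na(a) && (a < angle_lo || a > angle_hi)) ||
      d1 < d_lo || d1 > d_hi || d2 < d_lo || d2 > d_hi
  }
  out
}

#' Mark high outlier density
#'
#' Over the three-residue window {i-1, i, i+1} (within one segment), count
#' four conditions: c1 -- at least 2 residues carry a cis-nonPro/twisted
#' peptide-bond attribute; c2 -- at least 2 residues are CA-geometry
#' outliers; c3 -- at least 2 residues are covalent bond/angle outliers;
#' c4 -- all three residues lie in the high-psi band and at least one is a
#' Ramachandran outlier.  The residue has high outlier density iff two or
#' more conditions hold.  Truncated terminal windows evaluate c1-c3 over
#' the available residues and can never satisfy c4.
#'
#' @param evidence Data frame with logical columns `omega_attr`, `ca_geom`,
#'   `covalent`, `in_band`, `rama_outlier` (one row per residue).
#' @param segments Integer vector of segment ids, one per residue.
#' @return Logical vector, one element per residue.
#' @export
mark_outlier_density <- function(evidence, segments) {
  n <- nrow(evidence)
  out <- logical(n)
  for (i in seq_len(n)) {
    w <- (i - 1L):(i + 1L)
    w <- w[w >= 1L & w <= n]
    w <- w[segments[w] == segments[i]]
    full <- length(w) == 3L
    c1 <- sum(evidence$omega_attr[w], na.rm = TRUE) >= 2L
    c2 <- sum(evidence$ca_geom[w], na.rm = TRUE) >= 2L
    c3 <- sum(evidence$covalent[w], na.rm = TRUE) >= 2L
    c4 <- full && all(evidence$in_band[w]) && any(evidence$rama_outlier[w])
    out[i] <- (c1 + c2 + c3 + c4) >= 2L
  }
  out
}

#' Mark signature barbed-wire outliers
#'
#' A residue carries a signature outlier iff any of: s1 -- it is a
#' Ramachandran outlier inside the upper-right signature box (regardless of
#' packing); s2 -- it is a CA-geometry outlier in a low-pLDDT, unpacked
#' region; s3 -- it shares a peptide bond carrying a C-N-CA angle outlier,
#' a cis-nonPro bond, or any twisted bond (both sharers marked); s4 -- it
#' shares a cis-Pro bond and is itself low-pLDDT and unpacked (cis-Pro is
#' permitted in predictive regions).
#'
#' @param rama Result of [evaluate_ramachandran()] (per residue), with
#'   `status` possibly overridden by injection.
#' @param ca_geom Per-residue CA-geometry outlier logical.
#' @param bonds Peptide-bond table (internal; columns `i`, `j`, `kind`,
#'   `cnca_outlier`).
#' @param packed Per-residue packed verdict.
#' @param plddt Per-residue pLDDT.
#' @param plddt_high High-confidence threshold (default 70).
#' @return Logical vector, one element per residue.
#' @export
mark_signature_outliers <- function(rama, ca_geom, bonds, packed, plddt,
                                    plddt_high = 70) {
  n <- length(ca_geom)
  low_unpacked <- !is.na(plddt) & plddt < plddt_high & !packed
  sig <- rama$status == "outlier" & rama$in_signature_box            # s1
  sig <- sig | (ca_geom & low_unpacked)                              # s2
  if (nrow(bonds)) {
    s3_bond <- bonds$cnca_outlier | bonds$kind %in% c("cis_nonpro", "twisted")
    s3_bond[is.na(s3_bond)] <- FALSE
    hit <- unique(c(bonds$i[s3_bond], bonds$j[s3_bond]))
    sig[hit] <- TRUE                                                 # s3
    cis_pro <- bonds$kind %in% "cis_pro"
    hit4 <- unique(c(bonds$i[cis_pro], bonds$j[cis_pro]))
    sig[hit4] <- sig[hit4] | low_unpacked[hit4]                      # s4
  }
  sig
}
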