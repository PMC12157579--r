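# End-to-end analysis: validation + secondary structure + packing +
# classification, producing the per-residue annotation object every output
# renderer consumes.

#' Analyse a structure model
#'
#' Runs the full pipeline on a parsed model: backbone dihedrals, peptide
#' bond classes, covalent-geometry z-scores, Ramachandran evaluation,
#' CA-geometry flags, CA-based secondary structure, tertiary-contact
#' packing, the outlier-density and signature rules, the six-mode decision
#' tree, and run smoothing.
#'
#' @param model A `bw_model` (from [read_structure()] or
#'   [build_backbone()]).
#' @param cfg A [bw_config()].
#' @param inject Optional externally computed validation flags: a list with
#'   any of `rama_status` (named character vector, residue uid ->
#'   favored/allowed/outlier) and `ca_outliers` (character vector of
#'   residue uids).  Injected values override the bundled proxies.
#' @param radii Van der Waals radii table for the contact stage.
#' @return An object of class `bw_annotation`: list with `residues` (the
#'   per-residue annotation data frame), `bonds`, `measures`, `contacts`,
#'   `model` and `cfg`.
#' @export
bw_analyze <- function(model, cfg = bw_config(), inject = NULL,
                       radii = default_radii()) {
  stopifnot(inherits(model, "bw_model"))
  res <- model$residues
  n <- nrow(res)

  dih <- compute_backbone_dihedrals(model)
  geom <- validate_bond_geometry(model, z_cutoff = cfg$bond_z_cutoff)
  bonds <- peptide_bond_table(model, dih, geom,
                              cis_max = cfg$cis_max,
                              trans_min = cfg$trans_min)
  rama <- evaluate_ramachandran(dih$phi, dih$psi, residue_rama_class(model),
                                box = cfg$signature_box,
                                band = cfg$high_psi_band)
  if (!is.null(inject$rama_status)) {
    hit <- match(res$uid, names(inject$rama_status))
    rama$status[!is.na(hit)] <- unname(inject$rama_status[hit[!is.na(hit)]])
  }
  ca_geom <- flag_ca_geometry(model,
                              angle_lo = cfg$ca_angle_lo,
                              angle_hi = cfg$ca_angle_hi,
                              d_lo = cfg$ca_d_lo, d_hi = cfg$ca_d_hi,
                              inject = inject$ca_outliers)

  ss <- assign_secondary_structure(model)
  contacts <- find_contacts(model, radii = radii, ss = ss,
                            gap = cfg$contact_gap,
                            min_seq_sep = cfg$min_seq_sep)
  pack <- packing_score(model, contacts, ss,
                        cutoff_other = cfg$pack_cutoff_helix_coil,
                        cutoff_strand = cfg$pack_cutoff_strand,
                        half_window = (cfg$packing_window - 1L) %/% 2L)

  # per-residue peptide-bond attributes (both sharers inherit)
  omega_attr <- cis_pro_attr <- logical(n)
  if (nrow(bonds)) {
    bad_bond <- bonds$kind %in% c("cis_nonpro", "twisted")
    omega_attr[unique(c(bonds$i[bad_bond], bonds$j[bad_bond]))] <- TRUE
    cis_b <- bonds$kind %in% "cis_pro"
    cis_pro_attr[unique(c(bonds$i[cis_b], bonds$j[cis_b]))] <- TRUE
  }

  evidence <- data.frame(
    omega_attr = omega_attr,
    ca_geom = ca_geom,
    covalent = geom$covalent_outlier,
    in_band = rama$in_high_psi_band,
    rama_outlier = rama$status == "outlier"
  )
  high_density <- mark_outlier_density(evidence, res$segment)
  signature <- mark_signature_outliers(rama, ca_geom, bonds, pack$packed,
                                       res$plddt,
                                       plddt_high = cfg$plddt_high)

  mode_pre <- classify_residue(res$plddt, pack$packed, high_density,
                               signature, cfg)
  mode_pre[!res$eligible] <- NA_character_
  mode_post <- smooth_modes(mode_pre, res$segment,
                            max_run = cfg$smoothing_max_run)

  ann <- data.frame(
    uid = res$uid, chain = res$chain, resseq = res$resseq,
    icode = res$icode, resname = res$resname,
    plddt = res$plddt, eligible = res$eligible, segment = res$segment,
    phi = dih$phi, psi = dih$psi,
    ss = ss$ss, element_id = ss$element_id,
    score = pack$score, contact_count = pack$contact_count,
    window_heavy_atoms = pack$window_heavy_atoms, packed = pack$packed,
    rama_status = rama$status,
    in_signature_box = rama$in_signature_box,
    in_high_psi_band = rama$in_high_psi_band,
    omega_attr = omega_attr, cis_pro_attr = cis_pro_attr,
    ca_geom_outlier = ca_geom,
    covalent_outlier = geom$covalent_outlier,
    high_density = high_density, signature = signature,
    mode_pre = mode_pre, mode = mode_post,
    stringsAsFactors = FALSE
  )
  ann$lprocg <- lprocg_labels(ann, cfg)
  structure(list(residues = ann, bonds = bonds, measures = geom$measures,
                 contacts = contacts, model = model, cfg = cfg),
            class = "bw_annotation")
}

#' @export
print.bw_annotation <- function(x, ...) {
  census <- table(factor(x$residues$mode, levels = .BW_MODES))
  cat("<bw_annotation> ", nrow(x$residues), " residues\n", sep = "")
  for (m in .BW_MODES) cat(sprintf("  %-20s %d\n", m, census[[m]]))
  invisible(x)
}

# Lprocg: L low pLDDT, p unpacked, r Ramachandran outlier in the high-psi
# band, o omega attribute (cis-Pro only counts in low-pLDDT unpacked
# context), c CA-geometry outlier, g covalent-geometry outlier; '-' where
# the residue is not barbed-wire-like in that regard.
lprocg_labels <- function(ann, cfg = bw_config()) {
  L <- !is.na(ann$plddt) & ann$plddt < cfg$plddt_high
  p <- !ann$packed
  r <- ann$rama_status == "outlier" & ann$in_high_psi_band
  o <- ann$omega_attr | (ann$cis_pro_attr & L & p)
  cc <- ann$ca_geom_outlier
  g <- ann$covalent_outlier
  paste0(ifelse(L, "L", "-"), ifelse(p, "p", "-"), ifelse(r, "r", "-"),
         ifelse(o, "o", "-"), ifelse(cc, "c", "-"), ifelse(g, "g", "-"))
}
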