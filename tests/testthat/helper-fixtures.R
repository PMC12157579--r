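# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary fixtures.

# minimal PDB text: one chain of ALA residues from a torsion build
ideal_helix_model <- function(n = 12L, plddt = 90) {
  build_backbone(torsion_script(rep("ALA", n), phi = -57, psi = -47,
                                omega = 180, plddt = plddt))
}

extended_model <- function(n = 20L, plddt = 50, resname = "ALA") {
  build_backbone(torsion_script(rep(resname, n), phi = -120, psi = 120,
                                omega = 180, plddt = plddt))
}

# hand-written 3-residue ALA PDB text (fixed B = 65.0)
mini_pdb_text <- function(b_ca = 65, b_other = 65) {
  m <- build_backbone(torsion_script(rep("ALA", 3L), plddt = 0))
  at <- m$atoms
  sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), at$name, at$resname, at$chain, at$resseq,
    at$x, at$y, at$z, 1.00,
    ifelse(at$name == "CA", b_ca, b_other), at$element)
}

# smallest angular difference in degrees (handles the -180/+180 seam)
ang_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  abs(d)
}

# independent brute-force contact oracle: O(n^2) all-pairs scan
oracle_contacts <- function(model, radii = default_radii(), ss = NULL,
                            gap = 0.25, min_seq_sep = 4L) {
  at <- model$atoms
  n <- nrow(at)
  r <- unname(radii[toupper(at$element)])
  r[is.na(r)] <- 1.70
  res <- model$residues
  ord <- stats::ave(seq_len(nrow(res)), res$chain, FUN = seq_along)
  eid <- if (is.null(ss)) rep(NA_integer_, nrow(res)) else ss$element_id
  pairs <- list()
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      d <- sqrt((at$x[a] - at$x[b])^2 + (at$y[a] - at$y[b])^2 +
                  (at$z[a] - at$z[b])^2)
      if (d > r[a] + r[b] + gap) next
      ra <- at$res_index[a]; rb <- at$res_index[b]
      if (res$chain[ra] == res$chain[rb] &&
          abs(ord[ra] - ord[rb]) <= min_seq_sep) next
      if (!is.na(eid[ra]) && !is.na(eid[rb]) && eid[ra] == eid[rb]) next
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  if (!length(pairs)) return(character())
  sort(vapply(pairs, function(p) paste(p, collapse = "-"), character(1L)))
}

# minimal kinemage reader: groups, ball lists with colors, ball counts
parse_kinemage <- function(lines) {
  groups <- list()
  cur_group <- NULL
  cur_list <- NULL
  for (l in lines) {
    if (grepl("^@group", l)) {
      cur_group <- sub("^@group \\{([^}]*)\\}.*$", "\\1", l)
      groups[[cur_group]] <- list(dominant = grepl("dominant", l),
                                  balllists = list())
      cur_list <- NULL
    } else if (grepl("^@balllist", l)) {
      stopifnot(!is.null(cur_group))
      cur_list <- sub("^@balllist \\{([^}]*)\\}.*$", "\\1", l)
      color <- sub(".*color= *([a-z]+).*", "\\1", l)
      groups[[cur_group]]$balllists[[cur_list]] <-
        list(color = color, n = 0L, points = character())
    } else if (grepl("^@", l)) {
      cur_list <- NULL
    } else if (grepl("^\\{", l) && !is.null(cur_list)) {
      g <- groups[[cur_group]]
      pt <- g$balllists[[cur_list]]
      pt$n <- pt$n + 1L
      pt$points <- c(pt$points, sub("^\\{([^}]*)\\}.*$", "\\1", l))
      # coordinates must be three parseable numbers
      xyz <- strsplit(trimws(sub("^\\{[^}]*\\}", "", l)), "[[:space:]]+")[[1L]]
      stopifnot(length(xyz) == 3L, !anyNA(suppressWarnings(as.numeric(xyz))))
      g$balllists[[cur_list]] <- pt
      groups[[cur_group]] <- g
    }
  }
  groups
}
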