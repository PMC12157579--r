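# Synthetic decoy fixtures emulating AlphaFold2 failure modes: distorted
# high-psi coils with C-N-CA angle errors and cis/twisted peptides (barbed
# wire), isolated under-hydrogen-bonded secondary-structure elements
# (pseudostructure), poly-proline II stretches, and well-packed assemblies
# (predictive / near-predictive / unphysical cores).  Every fixture carries
# an assignable pLDDT profile and a manifest of expected per-residue modes
# (NA where no expectation is asserted, e.g. at termini).

.FIXTURE_KINDS <- c("predictive_bundle", "unpacked_helix",
                    "near_predictive_domain", "pseudostructure_helix",
                    "pseudostructure_strand", "polyproline_II",
                    "barbed_wire_coil", "unphysical_core")

#' Fixture kinds understood by [make_fixture()]
#' @return Character vector of kind names.
#' @export
fixture_kinds <- function() .FIXTURE_KINDS

# pose helpers -------------------------------------------------------------

# local extension of a constant-torsion 5-mer: d(CA1, CA5).  Small values
# mean the torsion pair sits on the tight-spiral diagonal of the box.
.band_extension <- local({
  cache <- new.env(parent = emptyenv())
  function(phi, psi) {
    # evaluate on a 1-degree grid so the memo is a pure function
    phi <- round(phi)
    psi <- round(psi)
    key <- paste(phi, psi)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    s <- torsion_script(rep("ALA", 5L), phi = phi, psi = psi)
    ca <- atom_coords(build_backbone(s), "CA")
    v <- vnorm(ca[5L, ] - ca[1L, ])
    cache[[key]] <- v
    v
  }
})

.rot_z <- function(deg) {
  a <- deg * .deg2rad
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

# n parallel copies of one scripted chain, stacked along z
.stack_chains <- function(resname, phi, psi, plddt, n_chains, spacing,
                          distort_chain = NULL, distortions = NULL) {
  models <- vector("list", n_chains)
  for (k in seq_len(n_chains)) {
    d <- if (!is.null(distort_chain) && k == distort_chain) distortions
         else NULL
    s <- torsion_script(resname, phi = phi, psi = psi, omega = 180,
                        plddt = plddt, chain = LETTERS[k], distortions = d)
    models[[k]] <- build_backbone(s, origin = c(0, 0, (k - 1L) * spacing))
  }
  do.call(combine_models, models)
}

#' Build a synthetic fixture with known expected modes
#'
#' Deterministic for a fixed seed.  The generated worlds are:
#' \describe{
#'   \item{predictive_bundle}{four-strand parallel assembly, pLDDT 85-95;
#'     interior residues are expected `predictive`.}
#'   \item{unpacked_helix}{isolated ideal alpha helix at pLDDT >= 90;
#'     expected `unpacked_high_plddt`.}
#'   \item{near_predictive_domain}{the four-strand assembly at pLDDT
#'     55-65; expected `near_predictive`.}
#'   \item{pseudostructure_helix}{isolated ideal helix at low pLDDT;
#'     expected `pseudostructure`.}
#'   \item{pseudostructure_strand}{isolated extended strand at low pLDDT;
#'     expected `pseudostructure`, zero signature outliers.}
#'   \item{polyproline_II}{all-PRO stretch at phi -75 / psi +150, low
#'     pLDDT; expected `pseudostructure`.}
#'   \item{barbed_wire_coil}{coil with psi drawn uniformly in (+60, +170)
#'     and phi in (-15, +170), twisted-omega and -4.5 sigma C-N-CA
#'     distortions on >= 40\% of residues, pLDDT in [20, 45]; expected
#'     `barbed_wire`.}
#'   \item{unphysical_core}{the packed assembly at low pLDDT with -4.5
#'     sigma C-N-CA distortions inside one chain; the distorted residues
#'     are expected `unphysical`, the clean chains `near_predictive`.}
#' }
#'
#' @param kind One of [fixture_kinds()].
#' @param seed Integer seed; identical seeds give byte-identical models.
#' @return List with `model` (a `bw_model`), `expected` (per-residue
#'   character vector of expected modes, `NA` where unasserted), `kind`,
#'   `seed`.
#' @export
make_fixture <- function(kind = fixture_kinds(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  strand_len <- 12L
  sheet_spacing <- 4.6
  expected <- NULL

  if (kind %in% c("predictive_bundle", "near_predictive_domain",
                  "unphysical_core")) {
    plddt <- switch(kind,
      predictive_bundle = stats::runif(strand_len, 85, 95),
      near_predictive_domain = stats::runif(strand_len, 55, 65),
      unphysical_core = stats::runif(strand_len, 38, 48))
    dist <- if (kind == "unphysical_core") {
      data.frame(res = 5:8, measure = "C-N-CA", offset = -4.5)
    } else NULL
    model <- .stack_chains(rep("ALA", strand_len), phi = -120, psi = 120,
                           plddt = round(plddt, 2), n_chains = 4L,
                           spacing = sheet_spacing,
                           distort_chain = if (!is.null(dist)) 2L else NULL,
                           distortions = dist)
    n <- nrow(model$residues)
    expected <- rep(NA_character_, n)
    interior <- rep(c(FALSE, FALSE, rep(TRUE, strand_len - 4L), FALSE, FALSE),
                    4L)
    expected[interior] <- switch(kind,
      predictive_bundle = "predictive",
      near_predictive_domain = "near_predictive",
      unphysical_core = "near_predictive")
    if (kind == "unphysical_core") {
      # distorted bonds enter residues 5..8 of chain B; both sharers of
      # each bond carry the signature, so 4..8 are expected unphysical
      expected[strand_len + 4:8] <- "unphysical"
    }
  } else if (kind %in% c("unpacked_helix", "pseudostructure_helix")) {
    len <- 16L
    plddt <- if (kind == "unpacked_helix") stats::runif(len, 90, 98)
             else stats::runif(len, 25, 45)
    s <- torsion_script(rep("ALA", len), phi = -57, psi = -47, omega = 180,
                        plddt = round(plddt, 2))
    model <- build_backbone(s)
    expected <- rep(NA_character_, len)
    expected[3:(len - 2L)] <- if (kind == "unpacked_helix")
      "unpacked_high_plddt" else "pseudostructure"
  } else if (kind == "pseudostructure_strand") {
    len <- 10L
    s <- torsion_script(rep("ALA", len), phi = -120, psi = 120, omega = 180,
                        plddt = round(stats::runif(len, 25, 40), 2))
    model <- build_backbone(s)
    expected <- rep(NA_character_, len)
    expected[3:(len - 2L)] <- "pseudostructure"
  } else if (kind == "polyproline_II") {
    len <- 10L
    s <- torsion_script(rep("PRO", len), phi = -75, psi = 150, omega = 180,
                        plddt = round(stats::runif(len, 22, 40), 2))
    model <- build_backbone(s)
    expected <- rep(NA_character_, len)
    expected[3:(len - 2L)] <- "pseudostructure"
  } else if (kind == "barbed_wire_coil") {
    len <- 30L
    # Torsions drawn uniformly from the high-psi band / signature box, but
    # -- as in the mode being emulated, whose wide rigid arcs carry
    # essentially no steric contacts -- draws are rejected when they would
    # curl or fold the chain onto itself: per-residue draws falling on the
    # tight-spiral diagonal of the box are resampled, and whole chains are
    # rebuilt while any CA-CA pair at sequence separation >= 5 approaches
    # within 9 A.
    tries <- 0L
    repeat {
      tries <- tries + 1L
      phi <- psi <- numeric(len)
      for (i in seq_len(len)) {
        repeat {
          p <- stats::runif(1, -14, 169)
          q <- stats::runif(1, 61, 169)
          if (.band_extension(p, q) > 9) break
        }
        phi[i] <- p
        psi[i] <- q
      }
      omega <- rep(180, len)
      # >= 40% of peptide bonds twisted; near-boundary values keep the
      # local chain direction while still classifying as twisted
      tw <- sort(sample(seq_len(len - 1L), size = ceiling(0.45 * len)))
      omega[tw] <- ifelse(seq_along(tw) %% 2L == 0L, -140, 140)
      cn <- sort(sample(seq(2L, len), size = ceiling(0.45 * len)))
      dist <- data.frame(res = cn, measure = "C-N-CA", offset = -4.5)
      s <- torsion_script(rep("ALA", len), phi = phi, psi = psi,
                          omega = omega,
                          plddt = round(stats::runif(len, 20, 45), 2),
                          distortions = dist)
      model <- build_backbone(s)
      ca <- atom_coords(model, "CA")
      d <- as.matrix(stats::dist(ca))
      sep <- abs(outer(seq_len(len), seq_len(len), "-"))
      if (min(d[sep >= 5L]) > 9 || tries >= 60L) break
    }
    expected <- rep(NA_character_, len)
    expected[3:(len - 2L)] <- "barbed_wire"
  }
  list(model = model, expected = expected, kind = kind, seed = seed)
}
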