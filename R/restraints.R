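# Bundled covalent restraint table (Engh & Huber style targets and sigmas)
# for protein backbone bonds and angles.  z = (observed - target) / sigma,
# and a measure is an outlier when |z| exceeds the configured cutoff
# (default 4, strict inequality).

#' Backbone covalent restraint table
#'
#' Target values and standard deviations for the backbone bond lengths and
#' bond angles validated by [validate_bond_geometry()].  The `C-N-CA` angle
#' and `C-N` bond span the peptide bond between consecutive residues; all
#' other measures are internal to one residue.
#'
#' @return A data frame with columns `measure`, `kind` (`bond`/`angle`),
#'   `target` (Angstrom or degrees) and `sigma`.
#' @export
#' @examples
#' backbone_restraints()
backbone_restraints <- function() {
  data.frame(
    measure = c("N-CA", "CA-C", "C-O", "C-N",
                "N-CA-C", "CA-C-N", "CA-C-O", "C-N-CA"),
    kind    = c("bond", "bond", "bond", "bond",
                "angle", "angle", "angle", "angle"),
    target  = c(1.458, 1.525, 1.231, 1.329,
                111.2, 116.2, 120.8, 121.7),
    sigma   = c(0.019, 0.021, 0.020, 0.014,
                2.8, 2.0, 1.7, 1.8),
    stringsAsFactors = FALSE
  )
}

restraint_lookup <- function(measure, restraints = backbone_restraints()) {
  i <- match(measure, restraints$measure)
  if (is.na(i)) stop("unknown restraint measure: ", measure, call. = FALSE)
  restraints[i, ]
}

#' Van der Waals radii used by the contact stage
#'
#' Probe-style heavy-atom radii.  Unknown elements fall back to 1.70
#' Angstrom with a warning.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
default_radii <- function() {
  c(C = 1.70, N = 1.625, O = 1.40, S = 1.80, P = 1.80, SE = 1.90)
}

vdw_radius <- function(elements, radii = default_radii()) {
  r <- radii[toupper(elements)]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ",
            paste(unique(elements[unknown]), collapse = ", "),
            "; using fallback radius 1.70 A", call. = FALSE)
    r[unknown] <- 1.70
  }
  unname(r)
}
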