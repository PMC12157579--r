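# Torsion-script backbone builder: constructs N/CA/C/O (+CB for non-GLY)
# coordinates from per-residue (phi, psi, omega) by sequential
# natural-extension (NeRF) placement using the bundled restraint-table
# geometry.  Controlled distortions are applied as offsets to named
# internal coordinates, so the validator recovers an injected k-sigma
# offset as z = k exactly (builder/validator round-trip).

#' Create a torsion script
#'
#' A torsion script is the recipe for a synthetic backbone: one row per
#' residue with the 3-letter name, the backbone torsions, and a pLDDT value
#' to store in the B-factor field.  `omega[i]` is the omega of the peptide
#' bond between residues `i` and `i+1` (the last value is unused).
#'
#' @param resname Character vector of 3-letter residue names.
#' @param phi,psi,omega Numeric vectors of torsions in degrees (recycled).
#' @param plddt Numeric vector of per-residue pLDDT in \[0,100\] (recycled).
#' @param chain Chain identifier for the built model.
#' @param distortions `NULL` or a data frame with columns `res` (residue
#'   index), `measure` (a [backbone_restraints()] measure name, offset in
#'   sigma units; or `phi`/`psi`/`omega`, offset in degrees) and `offset`.
#'   Peptide-bond measures (`C-N`, `C-N-CA`) at index `k` distort the bond
#'   *into* residue `k`; `CA-C-N` at `k` distorts the bond leaving `k`.
#' @return An object of class `bw_torsion_script`.
#' @export
torsion_script <- function(resname, phi = -120, psi = 120, omega = 180,
                           plddt = 50, chain = "A", distortions = NULL) {
  n <- length(resname)
  script <- list(
    resname = toupper(resname),
    phi = rep_len(phi, n), psi = rep_len(psi, n), omega = rep_len(omega, n),
    plddt = rep_len(plddt, n), chain = chain,
    distortions = distortions
  )
  if (!is.null(distortions)) {
    stopifnot(all(c("res", "measure", "offset") %in% names(distortions)))
    known <- c(backbone_restraints()$measure, "phi", "psi", "omega")
    bad <- setdiff(distortions$measure, known)
    if (length(bad)) {
      stop("unknown distortion measure(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(distortions$res < 1L | distortions$res > n)) {
      stop("distortion residue index out of range", call. = FALSE)
    }
  }
  class(script) <- "bw_torsion_script"
  script
}

# offset (sigma units for restraint measures, degrees for torsions) applied
# to measure `m` at residue `k`; 0 when none scripted
.distortion <- function(script, k, m) {
  d <- script$distortions
  if (is.null(d)) return(0)
  hit <- d$res == k & d$measure == m
  if (!any(hit)) return(0)
  sum(d$offset[hit])
}

#' Build Cartesian coordinates from a torsion script
#'
#' Residues are placed sequentially; the carbonyl O sits in the peptide
#' plane anti to the following N, and CB is placed with ideal tetrahedral
#' geometry (L-configuration) for non-GLY residues.  B-factors carry the
#' scripted pLDDT profile.
#'
#' @param script A [torsion_script()].
#' @param restraints Restraint table, see [backbone_restraints()].
#' @param origin 3-vector added to all coordinates (used to pose multi-part
#'   assemblies).
#' @param rotation 3x3 rotation matrix applied before translation.
#' @return A `bw_model` (segments populated).
#' @export
build_backbone <- function(script, restraints = backbone_restraints(),
                           origin = c(0, 0, 0), rotation = diag(3)) {
  stopifnot(inherits(script, "bw_torsion_script"))
  n <- length(script$resname)
  tv <- function(m) restraint_lookup(m, restraints)$target
  sv <- function(m) restraint_lookup(m, restraints)$sigma
  val <- function(k, m) tv(m) + .distortion(script, k, m) * sv(m)
  tor <- function(k, m) script[[m]][k] + .distortion(script, k, m)

  pos <- vector("list", n)  # each: named list of atom coords
  for (i in seq_len(n)) {
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- c(val(1L, "N-CA"), 0, 0)
      th <- val(1L, "N-CA-C") * .deg2rad
      C <- CA + val(1L, "CA-C") * c(-cos(th), sin(th), 0)
    } else {
      p <- pos[[i - 1L]]
      N <- nerf_place(p$N, p$CA, p$C,
                      val(i, "C-N"), val(i - 1L, "CA-C-N"),
                      tor(i - 1L, "psi"))
      CA <- nerf_place(p$CA, p$C, N,
                       val(i, "N-CA"), val(i, "C-N-CA"),
                       tor(i - 1L, "omega"))
      C <- nerf_place(p$C, N, CA,
                      val(i, "CA-C"), val(i, "N-CA-C"),
                      tor(i, "phi"))
    }
    O <- nerf_place(N, CA, C,
                    val(i, "C-O"), val(i, "CA-C-O"),
                    tor(i, "psi") + 180)
    atoms <- list(N = N, CA = CA, C = C, O = O)
    if (script$resname[i] != "GLY") {
      atoms$CB <- place_cb(N, CA, C)
    }
    pos[[i]] <- atoms
  }

  rows <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    for (nm in names(pos[[i]])) {
      serial <- serial + 1L
      xyz <- c(rotation %*% pos[[i]][[nm]]) + origin
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, altloc = "",
        resname = script$resname[i], chain = script$chain,
        resseq = i, icode = "",
        x = xyz[1L], y = xyz[2L], z = xyz[3L],
        b = script$plddt[i],
        element = substr(nm, 1L, 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  build_model(do.call(rbind, rows))
}

# CB from tetrahedral ideal geometry about CA (phi/psi invariant frame);
# sign of the out-of-plane component selects the L configuration.
place_cb <- function(N, CA, C, length = 1.53) {
  b1 <- N - CA
  b2 <- C - CA
  b1 <- b1 / vnorm(b1)
  b2 <- b2 / vnorm(b2)
  bis <- -(b1 + b2)
  bis <- bis / vnorm(bis)
  perp <- vcross(b2, b1)
  perp <- perp / vnorm(perp)
  CA + length * (cos(0.9553) * bis + sin(0.9553) * perp)  # 54.75 deg tilt
}

#' Combine several models into one multi-part assembly
#'
#' Concatenates the atoms of the given models (re-serialised) and rebuilds
#' the residue table and segments.  Chains must be distinct or residue
#' numbering non-overlapping.
#'
#' @param ... `bw_model` objects.
#' @return A single `bw_model`.
#' @export
combine_models <- function(...) {
  models <- list(...)
  atoms <- do.call(rbind, lapply(models, function(m) {
    a <- m$atoms
    a$res_index <- NULL
    a
  }))
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  build_model(atoms)
}
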