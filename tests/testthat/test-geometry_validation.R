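test_that("builder/dihedral round-trip recovers scripted torsions", {
  cases <- list(c(-57, -47, 180), c(-120, 120, 180), c(-75, 150, 180),
                c(60, 61, -90))
  for (cs in cases) {
    m <- build_backbone(torsion_script(rep("ALA", 8L), phi = cs[1L],
                                       psi = cs[2L], omega = cs[3L]))
    d <- compute_backbone_dihedrals(m)
    expect_lt(max(ang_diff(d$phi[2:8], cs[1L])), 1e-4)
    expect_lt(max(ang_diff(d$psi[1:7], cs[2L])), 1e-4)
    expect_lt(max(ang_diff(d$omega_next[1:7], cs[3L])), 1e-4)
  }
  # termini are undefined
  m <- ideal_helix_model(5L)
  d <- compute_backbone_dihedrals(m)
  expect_true(is.na(d$phi[1L]))
  expect_true(is.na(d$psi[5L]))
  expect_true(is.na(d$omega_next[5L]))
})

test_that("undistorted builds have |z| ~ 0 and injected k-sigma distortions recover z = k", {
  m0 <- ideal_helix_model(6L)
  g0 <- validate_bond_geometry(m0)
  expect_lt(max(abs(g0$measures$z)), 1e-6)

  for (k in c(-4.5, -4.0, 3.0)) {
    for (meas in c("C-N-CA", "N-CA", "CA-C-O")) {
      s <- torsion_script(rep("ALA", 6L), phi = -57, psi = -47,
                          distortions = data.frame(res = 4L, measure = meas,
                                                   offset = k))
      g <- validate_bond_geometry(build_backbone(s))
      hit <- g$measures[g$measures$measure == meas &
                          abs(g$measures$z) > 1e-6, , drop = FALSE]
      expect_equal(nrow(hit), 1L, info = paste(meas, k))
      expect_equal(hit$z, k, tolerance = 1e-3)
    }
  }
  # unknown distortion measure is an error
  expect_error(torsion_script("ALA", distortions = data.frame(
    res = 1L, measure = "CG-CD", offset = 1)), "unknown distortion")
})

test_that("covalent outliers use strict |z| > 4 and C-N-CA marks both bond sharers", {
  # the stated example: observed 114.5, target 121.7, sigma 1.8 -> z = -4,
  # not an outlier under the strict convention
  # the stated example: observed 114.5, target 121.7, sigma 1.8 -> z = -4,
  # not an outlier under the strict convention
  r <- backbone_restraints()
  cnca <- r[r$measure == "C-N-CA", ]
  expect_equal((114.5 - cnca$target) / cnca$sigma, -4.0)
  s <- torsion_script(rep("ALA", 5L), phi = -57, psi = -47,
                      distortions = data.frame(res = 3L, measure = "C-N-CA",
                                               offset = -4.0))
  g <- validate_bond_geometry(build_backbone(s))
  expect_equal(g$cnca_z[3L], -4.0, tolerance = 1e-6)
  expect_false(any(g$covalent_outlier))
  expect_false(any(g$cnca_outlier))

  s2 <- torsion_script(rep("ALA", 5L), phi = -57, psi = -47,
                       distortions = data.frame(res = 3L, measure = "C-N-CA",
                                                offset = -5.0))
  g2 <- validate_bond_geometry(build_backbone(s2))
  expect_equal(which(g2$covalent_outlier), c(2L, 3L))  # both sharers
  expect_true(g2$cnca_outlier[3L])
})

test_that("peptide-bond classes partition the omega circle", {
  expect_equal(classify_peptide_bond(180, "ALA"), "trans")
  expect_equal(classify_peptide_bond(10, "PRO"), "cis_pro")
  expect_equal(classify_peptide_bond(-90, "GLY"), "twisted")
  # stated boundary convention: |omega| <= 30 cis, >= 150 trans
  expect_equal(classify_peptide_bond(30, "ALA"), "cis_nonpro")
  expect_equal(classify_peptide_bond(-30, "PRO"), "cis_pro")
  expect_equal(classify_peptide_bond(150, "ALA"), "trans")
  expect_equal(classify_peptide_bond(-150, "ALA"), "trans")
  expect_equal(classify_peptide_bond(30.5, "ALA"), "twisted")
  expect_equal(classify_peptide_bond(149.5, "ALA"), "twisted")
  # property: every omega gets exactly one class
  set.seed(7)
  om <- stats::runif(200, -180, 180)
  cls <- classify_peptide_bond(om, "ALA")
  expect_false(anyNA(cls))
  expect_true(all(cls %in% c("trans", "cis_nonpro", "twisted")))
})

test_that("Ramachandran status, signature box and high-psi band", {
  # bundled-table contract points
  e <- evaluate_ramachandran(c(60, -57, -150), c(120, -47, 60), "general")
  expect_equal(e$status, c("outlier", "favored", "allowed"))
  expect_equal(e$in_signature_box, c(TRUE, FALSE, FALSE))
  expect_equal(e$in_high_psi_band, c(TRUE, FALSE, FALSE))
  # band constrains only psi; box bounds exclude phi = -120
  b <- evaluate_ramachandran(-120, 100, "general")
  expect_true(b$in_high_psi_band)
  expect_false(b$in_signature_box)

  # box/band bounds are open intervals: edges are outside
  edges <- evaluate_ramachandran(c(-15, 170, 0, 0), c(100, 100, 60, 170))
  expect_equal(edges$in_signature_box, rep(FALSE, 4L))
  expect_equal(edges$in_high_psi_band, c(TRUE, TRUE, FALSE, FALSE))
  inside <- evaluate_ramachandran(c(-14.999, 169.999), c(60.001, 169.999))
  expect_equal(inside$in_signature_box, rep(TRUE, 2L))

  # undefined torsions: unevaluable, both booleans false
  u <- evaluate_ramachandran(NA, 100)
  expect_equal(u$status, "unevaluable")
  expect_false(u$in_signature_box || u$in_high_psi_band)

  # class-specific: PPII favored for proline; alpha favored for general
  expect_equal(evaluate_ramachandran(-75, 150, "proline")$status, "favored")
  expect_equal(evaluate_ramachandran(-120, 120, "general")$status, "favored")
})

test_that("CA-geometry proxy flags distorted traces, never termini", {
  m <- ideal_helix_model(8L)
  expect_false(any(flag_ca_geometry(m)))

  # compress one CA-CA distance below 2.7 A
  at <- m$atoms
  ca4 <- which(at$name == "CA" & at$res_index == 4L)
  ca3 <- which(at$name == "CA" & at$res_index == 3L)
  dir <- c(at$x[ca4] - at$x[ca3], at$y[ca4] - at$y[ca3], at$z[ca4] - at$z[ca3])
  dir <- dir / sqrt(sum(dir^2))
  at[ca4, c("x", "y", "z")] <- as.numeric(at[ca3, c("x", "y", "z")]) + 2.0 * dir
  m2 <- barbedwire:::build_model(at[, setdiff(names(at), "res_index")])
  f <- flag_ca_geometry(m2)
  expect_true(f[3L] && f[4L])
  expect_false(f[1L])
  expect_false(f[8L])

  # injection overrides the proxy
  inj <- flag_ca_geometry(m, inject = m$residues$uid[5L])
  expect_equal(which(inj), 5L)
})

test_that("outlier-density rule matches brute-force enumeration of window states", {
  # independent oracle: literal 2-of-4 rule, conditions recounted by
  # explicit pair enumeration over the window
  oracle <- function(w) {
    # w: 3-row data.frame of evidence for a full interior window
    pairs2 <- function(v) {
      hits <- 0L
      for (a in 1:2) for (b in (a + 1):3) {
        if (v[a] && v[b]) hits <- hits + 1L
      }
      hits > 0L
    }
    c1 <- pairs2(w$omega_attr)
    c2 <- pairs2(w$ca_geom)
    c3 <- pairs2(w$covalent)
    c4 <- w$in_band[1L] && w$in_band[2L] && w$in_band[3L] &&
      (w$rama_outlier[1L] || w$rama_outlier[2L] || w$rama_outlier[3L])
    sum(c1, c2, c3, c4) >= 2L
  }
  # all 2^12 states of (omega, ca, cov, rama_outlier) x 3 residues; two
  # sweeps pin the in_band boolean to its extremes
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 12L))
  for (band_mode in c("all", "tied_to_outlier")) {
    for (g in seq_len(nrow(grid))) {
      v <- as.logical(grid[g, ])
      w <- data.frame(omega_attr = v[1:3], ca_geom = v[4:6],
                      covalent = v[7:9], rama_outlier = v[10:12])
      w$in_band <- if (band_mode == "all") rep(TRUE, 3L) else w$rama_outlier
      got <- mark_outlier_density(w, segments = rep(1L, 3L))[2L]
      expect_identical(got, oracle(w))
    }
  }
})

test_that("truncated terminal windows evaluate c1-c3 only", {
  # two-residue terminal window with no evidence
  w <- data.frame(omega_attr = c(FALSE, FALSE), ca_geom = c(FALSE, FALSE),
                  covalent = c(FALSE, FALSE), in_band = c(TRUE, TRUE),
                  rama_outlier = c(TRUE, TRUE))
  expect_false(any(mark_outlier_density(w, rep(1L, 2L))))
  # c4 alone is never enough, even satisfied maximally
  w3 <- data.frame(omega_attr = rep(FALSE, 3L), ca_geom = rep(FALSE, 3L),
                   covalent = rep(FALSE, 3L), in_band = rep(TRUE, 3L),
                   rama_outlier = rep(TRUE, 3L))
  expect_false(mark_outlier_density(w3, rep(1L, 3L))[2L])
  # two conditions (c1 + c3) suffice
  w2 <- data.frame(omega_attr = c(TRUE, TRUE, FALSE),
                   ca_geom = rep(FALSE, 3L),
                   covalent = c(TRUE, FALSE, TRUE),
                   in_band = rep(FALSE, 3L), rama_outlier = rep(FALSE, 3L))
  expect_true(mark_outlier_density(w2, rep(1L, 3L))[2L])
})

test_that("signature rules s1-s4 and their packing/pLDDT context", {
  rama <- function(status = "favored", box = FALSE) {
    data.frame(status = status, in_signature_box = box,
               in_high_psi_band = box)
  }
  nobonds <- data.frame(i = integer(), j = integer(), kind = character(),
                        cnca_outlier = logical())
  # s1: box Ramachandran outlier ignores packing and pLDDT
  expect_true(mark_signature_outliers(rama("outlier", TRUE), FALSE, nobonds,
                                      packed = TRUE, plddt = 65))
  # a non-box outlier is not a signature
  expect_false(mark_signature_outliers(rama("outlier", FALSE), FALSE, nobonds,
                                       packed = FALSE, plddt = 30))
  # s2: CA-geometry outlier only in low-pLDDT unpacked context
  expect_true(mark_signature_outliers(rama(), TRUE, nobonds, FALSE, 60))
  expect_false(mark_signature_outliers(rama(), TRUE, nobonds, TRUE, 60))
  expect_false(mark_signature_outliers(rama(), TRUE, nobonds, FALSE, 85))
  # s3: cis-nonPro marks both sharers regardless of context
  bonds <- data.frame(i = 1L, j = 2L, kind = "cis_nonpro",
                      cnca_outlier = FALSE)
  s <- mark_signature_outliers(rama(c("favored", "favored")), c(FALSE, FALSE),
                               bonds, packed = c(TRUE, TRUE),
                               plddt = c(85, 85))
  expect_equal(s, c(TRUE, TRUE))
  # s4: cis-Pro is permitted in predictive regions
  bonds_cp <- data.frame(i = 1L, j = 2L, kind = "cis_pro",
                         cnca_outlier = FALSE)
  s_hi <- mark_signature_outliers(rama(c("favored", "favored")),
                                  c(FALSE, FALSE), bonds_cp,
                                  packed = c(TRUE, TRUE), plddt = c(85, 85))
  expect_equal(s_hi, c(FALSE, FALSE))
  s_lo <- mark_signature_outliers(rama(c("favored", "favored")),
                                  c(FALSE, FALSE), bonds_cp,
                                  packed = c(FALSE, FALSE), plddt = c(40, 40))
  expect_equal(s_lo, c(TRUE, TRUE))
})

test_that("signature monotonicity: adding evidence never clears a signature", {
  set.seed(11)
  nobonds <- data.frame(i = integer(), j = integer(), kind = character(),
                        cnca_outlier = logical())
  for (rep in 1:50) {
    st <- sample(c("favored", "outlier"), 1L)
    box <- sample(c(TRUE, FALSE), 1L)
    ca <- sample(c(TRUE, FALSE), 1L)
    pk <- sample(c(TRUE, FALSE), 1L)
    pl <- stats::runif(1, 20, 95)
    rama <- data.frame(status = st, in_signature_box = box,
                       in_high_psi_band = box)
    base <- mark_signature_outliers(rama, ca, nobonds, pk, pl)
    # add evidence: force outlier status + box + CA outlier
    rama2 <- data.frame(status = "outlier", in_signature_box = TRUE,
                        in_high_psi_band = TRUE)
    more <- mark_signature_outliers(rama2, TRUE, nobonds, pk, pl)
    expect_true(!base || more)
  }
})
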