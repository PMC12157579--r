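test_that("Lprocg labels follow the letter mapping", {
  # clean near-predictive fixture: typical label L-----
  np <- make_fixture("near_predictive_domain", seed = 1L)
  ann <- bw_analyze(np$model)
  rec <- render_annotation(ann, "structured")
  interior <- rec$mode == "near_predictive" & !is.na(rec$mode)
  expect_true(any(interior))
  expect_true(all(rec$lprocg[interior] == "L-----"))

  # clean pseudostructure fixture: typical label Lp----
  ps <- make_fixture("pseudostructure_strand", seed = 1L)
  ann2 <- bw_analyze(ps$model)
  rec2 <- render_annotation(ann2, "structured")
  expect_true(all(rec2$lprocg[rec2$mode == "pseudostructure"] == "Lp----"))
  expect_false(any(ann2$residues$signature))

  # labels always match the Lprocg pattern
  for (a in list(ann, ann2)) {
    expect_true(all(grepl("^[L-][p-][r-][o-][c-][g-]$", a$residues$lprocg)))
  }

  # barbed wire with box outlier + twisted bond + C-N-CA outlier: Lpro-g
  bw <- make_fixture("barbed_wire_coil", seed = 1L)
  ann3 <- bw_analyze(bw$model)
  r3 <- ann3$residues
  hit <- r3$rama_status == "outlier" & r3$in_high_psi_band & r3$omega_attr &
    r3$covalent_outlier & !r3$ca_geom_outlier & !r3$packed
  expect_true(any(hit))
  expect_true(all(r3$lprocg[hit] == "Lpro-g"))
})

test_that("text and structured outputs agree record for record", {
  fx <- make_fixture("near_predictive_domain", seed = 2L)
  ann <- bw_analyze(fx$model)
  rec <- render_annotation(ann, "structured")
  txt <- render_annotation(ann, "text")
  expect_equal(length(txt) - 1L, nrow(rec))  # header + one line each
  for (k in c(1L, nrow(rec))) {
    expect_match(txt[k + 1L], rec$uid[k], fixed = TRUE)
    expect_match(txt[k + 1L], rec$lprocg[k], fixed = TRUE)
    expect_match(txt[k + 1L], rec$mode[k], fixed = TRUE)
  }
  js <- jsonlite::fromJSON(render_annotation(ann, "json"))
  expect_equal(js$uid, rec$uid)
  expect_equal(js$mode, rec$mode)
  expect_equal(js$lprocg, rec$lprocg)
})

test_that("kinemage output parses with one toggleable group per present mode", {
  pred <- make_fixture("predictive_bundle", seed = 1L)$model
  np <- make_fixture("near_predictive_domain", seed = 1L)$model
  np$atoms$x <- np$atoms$x + 60  # keep the parts apart
  np$atoms$chain <- chartr("ABCD", "EFGH", np$atoms$chain)
  both <- combine_models(pred, np)
  ann <- bw_analyze(both)
  kin <- render_kinemage(ann)
  parsed <- parse_kinemage(kin)
  census <- table(ann$residues$mode)
  expect_setequal(names(parsed), names(census))
  for (m in names(parsed)) {
    lists <- parsed[[m]]$balllists
    expect_equal(length(lists), 1L)
    expect_equal(lists[[1L]]$color, unname(mode_colors()[m]))
    expect_equal(lists[[1L]]$n, unname(census[[m]]))
  }
  # paper-caption colors
  expect_equal(unname(mode_colors()["predictive"]), "blue")
  expect_equal(unname(mode_colors()["near_predictive"]), "green")
  expect_equal(unname(mode_colors()["barbed_wire"]), "red")
  expect_equal(unname(mode_colors()["unphysical"]), "purple")

  # empty model: header only, zero groups
  empty <- ann
  empty$residues$mode <- NA_character_
  kin0 <- render_kinemage(empty)
  expect_true(any(grepl("^@kinemage", kin0)))
  expect_equal(length(parse_kinemage(kin0)), 0L)
})

test_that("selection file defaults to predictive + near-predictive and round-trips", {
  pred <- make_fixture("predictive_bundle", seed = 1L)$model
  ps <- make_fixture("pseudostructure_helix", seed = 1L)$model
  ps$atoms$x <- ps$atoms$x + 80
  ps$atoms$chain <- "E"
  both <- combine_models(pred, ps)
  ann <- bw_analyze(both)
  expect_true(all(c("predictive", "pseudostructure") %in% ann$residues$mode))

  sel <- write_selection_file(ann)
  m2 <- read_structure(sel, format = "pdb")
  keep_expected <- ann$residues$uid[ann$residues$mode %in%
                                      c("predictive", "near_predictive")]
  expect_setequal(m2$residues$uid, keep_expected)

  # all six modes: every input atom comes back
  sel_all <- write_selection_file(ann, modes = mode_labels())
  m3 <- read_structure(sel_all, format = "pdb")
  expect_equal(nrow(m3$atoms), nrow(both$atoms))

  # empty selection: error carrying a mode census
  expect_error(write_selection_file(ann, modes = "barbed_wire"),
               "census")
  expect_error(write_selection_file(ann, modes = "no_such_mode"),
               "unknown mode")
})

test_that("CLI runs end to end with phenix-style flags", {
  fx <- make_fixture("near_predictive_domain", seed = 1L)
  tmp_in <- tempfile(fileext = ".pdb")
  write_structure_subset(fx$model, fx$model$residues$uid, path = tmp_in)

  out_txt <- tempfile(fileext = ".txt")
  expect_equal(bwa_cli(c(tmp_in, "output.type=text", "--out", out_txt)), 0L)
  expect_true(file.exists(out_txt))
  expect_gt(length(readLines(out_txt)), nrow(fx$model$residues))

  out_kin <- tempfile(fileext = ".kin")
  bwa_cli(c(tmp_in, "--output-type", "kin", "--out", out_kin))
  expect_gt(length(parse_kinemage(readLines(out_kin))), 0L)

  out_sel <- tempfile(fileext = ".pdb")
  bwa_cli(c(tmp_in, "output.type=selection_file",
            "modes=near_predictive,predictive", "--out", out_sel))
  expect_gt(nrow(read_structure(out_sel)$residues), 0L)

  # config override: absurdly high packing cutoff flips modes to unpacked
  cfgf <- tempfile(fileext = ".json")
  writeLines('{"pack_cutoff_strand": 99, "pack_cutoff_helix_coil": 99}', cfgf)
  out_js <- tempfile(fileext = ".json")
  bwa_cli(c(tmp_in, "output.type=json", "--config", cfgf, "--out", out_js))
  js <- jsonlite::fromJSON(paste(readLines(out_js), collapse = "\n"))
  expect_false(any(js$mode %in% c("predictive", "near_predictive")))

  # injection channel: force Ramachandran status from outside
  injf <- tempfile(fileext = ".json")
  uid <- fx$model$residues$uid[6L]
  writeLines(jsonlite::toJSON(list(rama_status = stats::setNames(
    list("outlier"), uid)), auto_unbox = TRUE), injf)
  out_js2 <- tempfile(fileext = ".json")
  bwa_cli(c(tmp_in, "output.type=json", "--inject", injf, "--out", out_js2))
  js2 <- jsonlite::fromJSON(paste(readLines(out_js2), collapse = "\n"))
  expect_equal(js2$rama_status[js2$uid == uid], "outlier")

  # bad usage: nonzero status in standalone mode, error otherwise
  expect_equal(suppressMessages(bwa_cli(character(), standalone = TRUE)), 1L)
  expect_error(bwa_cli(c(tmp_in, "output.type=bogus")), "output.type")
})
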