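# Output renderers: per-residue annotations (text / JSON), kinemage markup
# with mode-colored CA balls and Lprocg labels, mode-filtered PDB subsets,
# and the command-line entry point.

.MODE_COLORS <- c(predictive = "blue", unpacked_high_plddt = "gray",
                  near_predictive = "green", pseudostructure = "gold",
                  barbed_wire = "red", unphysical = "purple")

#' Kinemage color per prediction mode
#' @return Named character vector mode -> kinemage palette token.
#' @export
mode_colors <- function() .MODE_COLORS

annotation_records <- function(ann) {
  r <- ann$residues[ann$residues$eligible, , drop = FALSE]
  data.frame(
    uid = r$uid, chain = r$chain, resseq = r$resseq, icode = r$icode,
    resname = r$resname, plddt = r$plddt,
    mode = r$mode, mode_pre = r$mode_pre, lprocg = r$lprocg,
    score = r$score, packed = r$packed, ss = r$ss,
    rama_status = r$rama_status, omega_attr = r$omega_attr,
    ca_geom_outlier = r$ca_geom_outlier,
    covalent_outlier = r$covalent_outlier,
    high_density = r$high_density, signature = r$signature,
    stringsAsFactors = FALSE
  )
}

#' Render per-residue annotations
#'
#' `format = "text"` gives an aligned whitespace table (one line per
#' eligible residue, chain order preserved); `format = "structured"`
#' returns the same records as a data frame suitable for
#' `jsonlite::toJSON()`; `format = "json"` returns the JSON text.
#'
#' @param ann A `bw_annotation`.
#' @param format One of `"text"`, `"structured"`, `"json"`.
#' @return Character vector of lines, a data frame, or a JSON string.
#' @export
render_annotation <- function(ann, format = c("text", "structured", "json")) {
  format <- match.arg(format)
  rec <- annotation_records(ann)
  if (format == "structured") return(rec)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(rec, dataframe = "rows",
                                         na = "null", digits = NA,
                                         pretty = TRUE)))
  }
  header <- sprintf("%-12s %-3s %6s %-20s %-20s %-6s %7s %-7s",
                    "residue", "aa", "plddt", "mode", "mode_pre", "lprocg",
                    "score", "ss")
  lines <- sprintf("%-12s %-3s %6.1f %-20s %-20s %-6s %7.3f %-7s",
                   rec$uid, rec$resname, rec$plddt, rec$mode, rec$mode_pre,
                   rec$lprocg, ifelse(is.na(rec$score), 0, rec$score),
                   rec$ss)
  c(header, lines)
}

#' Render kinemage markup
#'
#' One toggleable group per mode present in the model, each holding a ball
#' list at the CA positions in the mode's caption color (predictive blue,
#' unpacked high-pLDDT gray, near-predictive green, pseudostructure gold,
#' barbed wire red, unphysical purple), plus a label list with the
#' per-residue Lprocg strings.
#'
#' @param ann A `bw_annotation`.
#' @param ball_radius Ball radius in Angstrom.
#' @return Character vector of kinemage lines.
#' @export
render_kinemage <- function(ann, ball_radius = 0.4) {
  rec <- ann$residues[ann$residues$eligible & !is.na(ann$residues$mode), ,
                      drop = FALSE]
  ca <- atom_coords(ann$model, "CA")
  out <- c("@kinemage 1",
           "@title {AlphaFold2 prediction-mode markup}",
           "@onewidth")
  idx_all <- which(ann$model$residues$uid %in% rec$uid)
  for (m in .BW_MODES) {
    sel <- which(rec$mode == m)
    if (!length(sel)) next
    ridx <- match(rec$uid[sel], ann$model$residues$uid)
    out <- c(out, sprintf("@group {%s} dominant", m),
             sprintf("@balllist {%s CA} color= %s radius= %.2f",
                     m, .MODE_COLORS[[m]], ball_radius))
    out <- c(out, sprintf("{%s %s %s} %.3f %.3f %.3f",
                          rec$uid[sel], rec$resname[sel], rec$lprocg[sel],
                          ca[ridx, 1L], ca[ridx, 2L], ca[ridx, 3L]))
    out <- c(out, sprintf("@labellist {%s labels} color= white", m))
    out <- c(out, sprintf("{%s} %.3f %.3f %.3f",
                          rec$lprocg[sel],
                          ca[ridx, 1L], ca[ridx, 2L], ca[ridx, 3L]))
  }
  out
}

#' Write a mode-filtered structure file
#'
#' Keeps residues whose post-smoothing mode is in `modes` (default:
#' predictive and near-predictive, the recommended molecular-replacement
#' preparation) and delegates to [write_structure_subset()].
#'
#' @param ann A `bw_annotation`.
#' @param modes Character vector of mode names to keep.
#' @param path Optional output path.
#' @return PDB lines (invisibly when written to file).
#' @export
write_selection_file <- function(ann,
                                 modes = c("predictive", "near_predictive"),
                                 path = NULL) {
  bad <- setdiff(modes, .BW_MODES)
  if (length(bad)) {
    stop("unknown mode(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- ann$residues
  keep <- res$uid[!is.na(res$mode) & res$mode %in% modes]
  if (!length(keep)) {
    census <- table(factor(res$mode, levels = .BW_MODES))
    stop("selection is empty for modes {",
         paste(modes, collapse = ", "), "}; mode census: ",
         paste(sprintf("%s=%d", names(census), census), collapse = ", "),
         call. = FALSE)
  }
  write_structure_subset(ann$model, keep, path = path)
}

#' Command-line entry point
#'
#' Phenix-style interface: positional input path, `output.type=` (or
#' `--output-type`) in `{text, json, kin, selection_file}`, `modes=` (or
#' `--modes`) as comma-separated mode names, `--out` for the output path
#' (default stdout), `--config` for a JSON file of [bw_config()] overrides,
#' `--inject` for a JSON file of external validation flags
#' (`{"rama_status": {"A:5:": "outlier"}, "ca_outliers": ["A:6:"]}`).
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly (0 on success); errors print a message
#'   and return nonzero instead of throwing when `standalone = TRUE`.
#' @param standalone When `TRUE` (script use), errors are caught and
#'   reported as a nonzero status; when `FALSE` (interactive/test use)
#'   they propagate.
#' @export
bwa_cli <- function(args = commandArgs(trailingOnly = TRUE),
                    standalone = FALSE) {
  run <- function() {
    opt <- list(output_type = "text",
                modes = c("predictive", "near_predictive"),
                out = NULL, config = NULL, inject = NULL, input = NULL)
    i <- 1L
    while (i <= length(args)) {
      a <- args[i]
      grab <- function() {
        if (i + 1L > length(args)) stop("missing value for ", a, call. = FALSE)
        i <<- i + 1L
        args[i]
      }
      if (grepl("^output\\.type=", a)) {
        opt$output_type <- sub("^output\\.type=", "", a)
      } else if (a == "--output-type") {
        opt$output_type <- grab()
      } else if (grepl("^modes=", a)) {
        opt$modes <- strsplit(sub("^modes=", "", a), ",")[[1L]]
      } else if (a == "--modes") {
        opt$modes <- strsplit(grab(), ",")[[1L]]
      } else if (a == "--out") {
        opt$out <- grab()
      } else if (a == "--config") {
        opt$config <- grab()
      } else if (a == "--inject") {
        opt$inject <- grab()
      } else if (grepl("^--", a)) {
        stop("unknown option: ", a, call. = FALSE)
      } else {
        if (!is.null(opt$input)) stop("multiple input paths given", call. = FALSE)
        opt$input <- a
      }
      i <- i + 1L
    }
    if (is.null(opt$input)) stop("no input structure file given", call. = FALSE)
    if (!opt$output_type %in% c("text", "json", "kin", "selection_file")) {
      stop("output.type must be one of text, json, kin, selection_file",
           call. = FALSE)
    }
    cfg <- bw_config()
    if (!is.null(opt$config)) {
      over <- jsonlite::fromJSON(opt$config)
      cfg <- do.call(bw_config, over)
    }
    inject <- NULL
    if (!is.null(opt$inject)) {
      inj <- jsonlite::fromJSON(opt$inject)
      inject <- list(
        rama_status = if (!is.null(inj$rama_status)) unlist(inj$rama_status),
        ca_outliers = inj$ca_outliers
      )
    }
    model <- read_structure(opt$input)
    ann <- bw_analyze(model, cfg = cfg, inject = inject)
    out_lines <- switch(opt$output_type,
      text = render_annotation(ann, "text"),
      json = render_annotation(ann, "json"),
      kin = render_kinemage(ann),
      selection_file = write_selection_file(ann, modes = opt$modes)
    )
    if (is.null(opt$out)) {
      cat(out_lines, sep = "\n")
    } else {
      writeLines(out_lines, opt$out)
    }
    0L
  }
  if (standalone) {
    status <- tryCatch(run(), error = function(e) {
      message("barbed_wire_analysis error: ", conditionMessage(e))
      1L
    })
  } else {
    status <- run()
  }
  invisible(status)
}
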