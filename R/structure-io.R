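# Structure input/output: parse PDB/mmCIF models into the internal
# structure model, detect peptide-bond continuity, and write residue-subset
# PDB files.
#
# The internal model (class "bw_model") is a list of two data frames:
#   $atoms    one row per retained heavy atom (serial, name, resname, chain,
#             resseq, icode, x, y, z, b, element, res_index)
#   $residues one row per (chain, resseq, icode): resname, plddt, has_ca,
#             eligible (N+CA+C present), segment (NA until segment_chain()),
#             uid ("chain:resseq:icode")
# Hydrogens, waters and non-polymer entities are dropped on input; only the
# first model of a multi-model file is read and altloc 'A' (or blank) wins.

.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL", "UNK")

residue_uid <- function(chain, resseq, icode) {
  icode[is.na(icode)] <- ""
  paste(chain, resseq, icode, sep = ":")
}

infer_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  two <- toupper(substr(nm, 1L, 2L))
  el <- toupper(substr(nm, 1L, 1L))
  el[two == "SE"] <- "SE"
  el
}

#' Read a structure model with per-residue pLDDT
#'
#' Parses a PDB or mmCIF file (or literal text) into the internal structure
#' model.  The per-residue pLDDT is taken from the B-factor of the CA atom,
#' following the AlphaFold convention of storing confidence in the B-factor
#' field.  Hydrogens, waters and non-polymer (HETATM) entities are dropped;
#' only the first model of a multi-model file is used, and alternate
#' location 'A' (or blank) wins.
#'
#' @param source Path to a structure file, or a character vector of file
#'   lines (anything containing a newline or of length > 1 is treated as
#'   literal text).
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (sniffed from the file
#'   extension and content).
#' @return A `bw_model` object; see [segment_chain()] for the continuity
#'   pass that windowed analyses require.
#' @export
read_structure <- function(source, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  is_text <- length(source) > 1L || grepl("\n", source[1L], fixed = TRUE)
  lines <- if (is_text) {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    if (!file.exists(source)) stop("no such file: ", source, call. = FALSE)
    readLines(source, warn = FALSE)
  }
  if (format == "auto") {
    format <- if ((!is_text && grepl("\\.cif$|\\.mmcif$", source,
                                     ignore.case = TRUE)) ||
                  any(grepl("^_atom_site\\.", lines)) ||
                  any(grepl("^data_", lines[seq_len(min(5L, length(lines)))])))
      "mmcif" else "pdb"
  }
  atoms <- if (format == "pdb") parse_pdb_atoms(lines) else parse_cif_atoms(lines)
  if (nrow(atoms) == 0L) {
    stop("no polymer heavy atoms found; unparseable or empty ", format,
         " input", call. = FALSE)
  }
  build_model(atoms)
}

parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  # first model only
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  keep <- substr(lines, 1L, 6L) == "ATOM  "
  ln <- lines[keep]
  if (!length(ln)) return(empty_atom_frame())
  f <- function(a, b) trimws(substr(ln, a, b))
  atoms <- data.frame(
    serial  = suppressWarnings(as.integer(f(7, 11))),
    name    = f(13, 16),
    altloc  = f(17, 17),
    resname = f(18, 20),
    chain   = f(22, 22),
    resseq  = suppressWarnings(as.integer(f(23, 26))),
    icode   = f(27, 27),
    x = suppressWarnings(as.numeric(f(31, 38))),
    y = suppressWarnings(as.numeric(f(39, 46))),
    z = suppressWarnings(as.numeric(f(47, 54))),
    b = suppressWarnings(as.numeric(f(61, 66))),
    element = toupper(f(77, 78)),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) || anyNA(atoms$resseq)) {
    stop("malformed PDB ATOM record(s): non-numeric coordinate or residue number",
         call. = FALSE)
  }
  atoms$element[atoms$element == ""] <- infer_element(atoms$name[atoms$element == ""])
  filter_atoms(atoms)
}

# Minimal mmCIF atom_site reader: locates the _atom_site loop and splits its
# rows on whitespace (quoted tokens are tolerated but not expected in
# coordinate rows).
parse_cif_atoms <- function(lines) {
  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx)) return(empty_atom_frame())
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  first_row <- max(tag_idx) + 1L
  rows <- character()
  for (i in first_row:length(lines)) {
    l <- trimws(lines[i])
    if (l == "" ) next
    if (startsWith(l, "#") || startsWith(l, "_") || startsWith(l, "loop_") ||
        startsWith(l, "data_")) break
    rows <- c(rows, l)
  }
  if (!length(rows)) return(empty_atom_frame())
  mat <- do.call(rbind, lapply(strsplit(rows, "[[:space:]]+"), function(x) {
    length(x) <- length(tags)
    x
  }))
  colnames(mat) <- tags
  col <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(mat[, nm])
    rep(NA_character_, nrow(mat))
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  model_num <- col("pdbx_PDB_model_num")
  if (!all(is.na(model_num))) {
    first <- model_num[!is.na(model_num)][1L]
    keep <- is.na(model_num) | model_num == first
    mat <- mat[keep, , drop = FALSE]
    col <- function(...) {
      for (nm in c(...)) if (nm %in% tags) return(mat[, nm])
      rep(NA_character_, nrow(mat))
    }
  }
  clean <- function(v) {
    v[v %in% c(".", "?")] <- ""
    v
  }
  group <- col("group_PDB")
  atoms <- data.frame(
    serial  = suppressWarnings(as.integer(col("id"))),
    name    = clean(col("auth_atom_id", "label_atom_id")),
    altloc  = clean(col("label_alt_id")),
    resname = clean(col("auth_comp_id", "label_comp_id")),
    chain   = clean(col("auth_asym_id", "label_asym_id")),
    resseq  = suppressWarnings(as.integer(col("auth_seq_id", "label_seq_id"))),
    icode   = clean(col("pdbx_PDB_ins_code")),
    x = num(col("Cartn_x")), y = num(col("Cartn_y")), z = num(col("Cartn_z")),
    b = num(col("B_iso_or_equiv")),
    element = toupper(clean(col("type_symbol"))),
    stringsAsFactors = FALSE
  )
  atoms$name <- gsub('"', "", atoms$name)
  if (!all(is.na(group))) atoms <- atoms[group == "ATOM", , drop = FALSE]
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) || anyNA(atoms$resseq)) {
    stop("malformed mmCIF atom_site row(s)", call. = FALSE)
  }
  blank_el <- atoms$element == "" | is.na(atoms$element)
  atoms$element[blank_el] <- infer_element(atoms$name[blank_el])
  filter_atoms(atoms)
}

empty_atom_frame <- function() {
  data.frame(serial = integer(), name = character(), altloc = character(),
             resname = character(), chain = character(), resseq = integer(),
             icode = character(), x = numeric(), y = numeric(), z = numeric(),
             b = numeric(), element = character(), stringsAsFactors = FALSE)
}

filter_atoms <- function(atoms) {
  keep <- !(atoms$element %in% c("H", "D")) &
    !(atoms$resname %in% .WATER_NAMES) &
    atoms$resname %in% .AA3 &
    (atoms$altloc %in% c("", "A"))
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

build_model <- function(atoms) {
  uid <- residue_uid(atoms$chain, atoms$resseq, atoms$icode)
  # preserve file order of first appearance
  res_index <- match(uid, unique(uid))
  atoms$res_index <- res_index
  first <- !duplicated(res_index)
  residues <- data.frame(
    chain = atoms$chain[first],
    resseq = atoms$resseq[first],
    icode = atoms$icode[first],
    resname = atoms$resname[first],
    uid = uid[first],
    stringsAsFactors = FALSE
  )
  n <- nrow(residues)
  residues$plddt <- NA_real_
  residues$has_ca <- FALSE
  residues$eligible <- FALSE
  residues$segment <- NA_integer_
  is_ca <- atoms$name == "CA"
  ca_res <- atoms$res_index[is_ca]
  residues$has_ca[ca_res] <- TRUE
  residues$plddt[ca_res] <- atoms$b[is_ca]
  has <- function(nm) {
    out <- logical(n)
    out[unique(atoms$res_index[atoms$name == nm])] <- TRUE
    out
  }
  residues$eligible <- has("N") & has("CA") & has("C")
  bad <- which(residues$has_ca &
                 (is.na(residues$plddt) | residues$plddt < 0 | residues$plddt > 100))
  if (length(bad)) {
    stop("pLDDT (CA B-factor) outside [0,100] at residue ",
         paste(residues$uid[bad], collapse = ", "), call. = FALSE)
  }
  # warn on heterogeneous B within a residue (third-party edits)
  rng <- tapply(atoms$b, atoms$res_index, function(b) diff(range(b)))
  het <- which(!is.na(rng) & rng > 1e-6)
  if (length(het)) {
    warning("heterogeneous B-factors within residue(s) ",
            paste(utils::head(residues$uid[het], 5L), collapse = ", "),
            if (length(het) > 5L) " ..." else "",
            "; pLDDT taken from the CA atom", call. = FALSE)
  }
  model <- structure(list(atoms = atoms, residues = residues),
                     class = "bw_model")
  segment_chain(model)
}

#' @export
print.bw_model <- function(x, ...) {
  cat("<bw_model> ", nrow(x$residues), " residues, ", nrow(x$atoms),
      " heavy atoms, ",
      length(unique(x$residues$chain)), " chain(s), ",
      max(c(x$residues$segment, 0L), na.rm = TRUE), " segment(s)\n", sep = "")
  invisible(x)
}

# Coordinates of one named atom per residue (n x 3 matrix, NA rows when the
# atom is absent).
atom_coords <- function(model, atom_name) {
  n <- nrow(model$residues)
  out <- matrix(NA_real_, n, 3L)
  sel <- model$atoms$name == atom_name
  idx <- model$atoms$res_index[sel]
  keep <- !duplicated(idx)
  out[idx[keep], ] <- as.matrix(model$atoms[sel, c("x", "y", "z")])[keep, , drop = FALSE]
  out
}

#' Partition a model into peptide-bonded segments
#'
#' Consecutive residues share a segment iff they are in the same chain and
#' the C(i)-N(i+1) distance is at most 2.5 Angstrom (generous versus the
#' ~1.33 Angstrom ideal, to tolerate distorted low-confidence geometry while
#' still splitting true chain breaks).  Windowed analyses (packing windows,
#' outlier-density windows, smoothing) never cross segment boundaries.
#'
#' @param model A `bw_model`.
#' @param max_c_n Continuity threshold on the C-N distance, Angstrom.
#' @return The model with `residues$segment` populated (1-based, maximal runs).
#' @export
segment_chain <- function(model, max_c_n = 2.5) {
  res <- model$residues
  n <- nrow(res)
  if (n == 0L) return(model)
  cpos <- atom_coords(model, "C")
  npos <- atom_coords(model, "N")
  seg <- integer(n)
  seg[1L] <- 1L
  if (n > 1L) {
    for (i in 2L:n) {
      linked <- res$chain[i] == res$chain[i - 1L] &&
        !anyNA(cpos[i - 1L, ]) && !anyNA(npos[i, ]) &&
        vnorm(cpos[i - 1L, ] - npos[i, ]) <= max_c_n
      seg[i] <- if (linked) seg[i - 1L] else seg[i - 1L] + 1L
    }
  }
  model$residues$segment <- seg
  model
}

#' Write a residue subset as PDB text
#'
#' Emits standard 80-column ATOM records for the kept residues, preserving
#' the original coordinates, B-values and atom ordering, with TER records at
#' chain ends.
#'
#' @param model A `bw_model`.
#' @param keep Character vector of residue uids (`chain:resseq:icode`), or a
#'   logical/integer index into `model$residues`.
#' @param path Optional file path; when `NULL` the PDB text is returned.
#' @return Character vector of PDB lines (invisibly when written to a file).
#' @export
write_structure_subset <- function(model, keep, path = NULL) {
  res <- model$residues
  if (is.character(keep)) {
    missing <- setdiff(keep, res$uid)
    if (length(missing)) {
      stop("unknown residue uid(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    keep_idx <- which(res$uid %in% keep)
  } else if (is.logical(keep)) {
    keep_idx <- which(keep)
  } else {
    keep_idx <- as.integer(keep)
  }
  if (!length(keep_idx)) {
    stop("refusing to write an empty model: no residues selected",
         call. = FALSE)
  }
  at <- model$atoms[model$atoms$res_index %in% keep_idx, , drop = FALSE]
  lines <- character(0)
  serial <- 0L
  prev_chain <- NULL
  fmt_atom_name <- function(name, element) {
    # column 13-16: element right-justified in 13-14 for 1-letter elements
    if (nchar(name) >= 4L) return(substr(name, 1L, 4L))
    if (nchar(element) == 1L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  }
  out <- vector("character", nrow(at) + length(unique(at$chain)) + 1L)
  k <- 0L
  for (i in seq_len(nrow(at))) {
    if (!is.null(prev_chain) && at$chain[i] != prev_chain) {
      k <- k + 1L
      out[k] <- "TER"
    }
    prev_chain <- at$chain[i]
    serial <- serial + 1L
    k <- k + 1L
    out[k] <- sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial %% 100000L, fmt_atom_name(at$name[i], at$element[i]), "",
      at$resname[i], at$chain[i], at$resseq[i],
      ifelse(at$icode[i] == "", " ", at$icode[i]),
      at$x[i], at$y[i], at$z[i], 1.00, at$b[i], at$element[i])
  }
  k <- k + 1L
  out[k] <- "TER"
  k <- k + 1L
  out[k] <- "END"
  out <- out[seq_len(k)]
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
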