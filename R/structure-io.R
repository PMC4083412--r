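#' Construct a structure object from atom and residue tables
#'
#' Low-level constructor used by [parse_pdb()] and by the synthetic
#' structure generators. Most users should start from [parse_pdb()].
#'
#' @param residues data.frame with columns `chain`, `resno` (integer),
#'   `ins` (insertion code, `""` when absent) and `aa` (three-letter code).
#' @param atoms data.frame with columns `res_idx` (row index into
#'   `residues`), `name`, `element`, `x`, `y`, `z`, `occupancy`.
#' @param pdb_id identifier carried through to outputs.
#' @param chain chain identifier of the selected chain.
#' @return an object of class `rin_structure` with fields `residues`
#'   (including `ss`, `asa`, `rsa` columns, `NA` until assigned), `atoms`,
#'   `pdb_id`, `chain`.
#' @export
new_structure <- function(residues, atoms, pdb_id = "UNKN", chain = "A") {
  stopifnot(is.data.frame(residues), is.data.frame(atoms))
  if (nrow(residues) == 0L) stop("empty structure: no standard residues")
  if (!all(is_standard_aa(residues$aa)))
    stop("non-standard residue in residue table")
  if (!all(atoms$res_idx %in% seq_len(nrow(residues))))
    stop("atom table references unknown residue index")
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite atom coordinate")
  if (any(tabulate(atoms$res_idx, nrow(residues)) == 0L))
    stop("residue with no atoms")
  residues$ins <- as.character(residues$ins)
  residues$key <- paste0(residues$chain, "/", residues$resno, residues$ins)
  if (anyDuplicated(residues$key))
    stop("duplicate residue key: ", residues$key[duplicated(residues$key)][1])
  residues$ss <- if (is.null(residues$ss)) NA_character_ else residues$ss
  residues$asa <- if (is.null(residues$asa)) NA_real_ else residues$asa
  residues$rsa <- if (is.null(residues$rsa)) NA_real_ else residues$rsa
  out <- list(pdb_id = pdb_id, chain = chain,
              residues = residues, atoms = atoms)
  class(out) <- "rin_structure"
  out
}

#' @export
print.rin_structure <- function(x, ...) {
  cat(sprintf("<rin_structure> %s chain %s: %d residues, %d atoms\n",
              x$pdb_id, x$chain, nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

#' @export
length.rin_structure <- function(x) nrow(x$residues)

#' One-letter sequence of a structure
#' @param s an `rin_structure`.
#' @return character scalar, one letter per residue.
#' @export
structure_sequence <- function(s) {
  paste(aa_three_to_one(s$residues$aa), collapse = "")
}

# -- PDB parsing ------------------------------------------------------------

pdb_source_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE))
  }
}

# Return the lines of the requested MODEL block (0-based index); a file
# without MODEL records is treated as a single model 0.
slice_model <- function(lines, model_index) {
  starts <- grep("^MODEL ", lines)
  if (length(starts) == 0L) {
    if (model_index != 0L) stop("model not found: ", model_index)
    return(lines)
  }
  if (model_index + 1L > length(starts))
    stop("model not found: ", model_index)
  ends <- grep("^ENDMDL", lines)
  s <- starts[model_index + 1L]
  e <- ends[ends > s][1]
  if (is.na(e)) e <- length(lines)
  lines[(s + 1L):(e - 1L)]
}

validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM |HETATM)", lines)
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad))
    stop("format error at line ", bad[1], ": truncated coordinate record")
  for (i in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz))
      stop("format error at line ", i, ": unreadable coordinates")
  }
  invisible(TRUE)
}

#' Parse a single chain from a PDB file
#'
#' Reads PDB-format text (a path or the text itself) and returns the
#' requested chain of the requested model. Alternate locations are
#' resolved per atom by highest occupancy (ties broken by file order);
#' HETATM records, waters and non-standard residues are dropped;
#' hydrogens are retained when present.
#'
#' @param source path to a PDB file, or PDB-format text.
#' @param chain chain identifier; defaults to the first chain found.
#' @param model_index 0-based model number (for multi-model files).
#' @return an [new_structure()] object.
#' @export
parse_pdb <- function(source, chain = NULL, model_index = 0L) {
  lines <- pdb_source_lines(source)
  lines <- slice_model(lines, model_index)
  validate_pdb_lines(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- tryCatch(bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("format error: ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no ATOM records")
  if (is.null(chain)) chain <- at$chain[1]
  if (!chain %in% at$chain) stop("chain not found: ", chain)
  at <- at[at$chain == chain, , drop = FALSE]
  at <- at[is_standard_aa(at$resid), , drop = FALSE]
  if (nrow(at) == 0L)
    stop("empty structure: no standard residues in chain ", chain)

  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  at$occ <- ifelse(is.na(at$o), 1, at$o)
  rkey <- paste0(at$resno, "|", at$ins)
  akey <- paste0(rkey, "|", at$elety)
  # altloc resolution: highest occupancy per (residue, atom name), ties by
  # file order (stable sort keeps first encountered on equal occupancy)
  ord <- order(match(akey, unique(akey)), -at$occ)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste0(at$resno, "|", at$ins, "|", at$elety)), ,
           drop = FALSE]
  at <- at[order(match(paste0(at$resno, "|", at$ins), unique(rkey))), ,
           drop = FALSE]

  rk <- paste0(at$resno, "|", at$ins)
  urk <- unique(rk)
  res_idx <- match(rk, urk)
  first <- match(urk, rk)
  residues <- data.frame(
    chain = chain,
    resno = at$resno[first],
    ins = at$ins[first],
    aa = at$resid[first],
    stringsAsFactors = FALSE
  )
  element <- at$elesy
  element[is.na(element) | element == ""] <-
    substr(gsub("[0-9]", "", at$elety[is.na(element) | element == ""]), 1, 1)
  atoms <- data.frame(
    res_idx = res_idx,
    name = at$elety,
    element = element,
    x = at$x, y = at$y, z = at$z,
    occupancy = at$occ,
    stringsAsFactors = FALSE
  )
  pdb_id <- if (length(source) == 1L && !grepl("\n", source))
    sub("\\.pdb$", "", basename(source)) else "UNKN"
  new_structure(residues, atoms, pdb_id = pdb_id, chain = chain)
}

#' Write a structure back to PDB format
#'
#' @param s an `rin_structure`.
#' @param path optional output file; when `NULL` the PDB text is returned.
#' @return the PDB text, invisibly when written to a file.
#' @export
write_pdb <- function(s, path = NULL) {
  r <- s$residues[s$atoms$res_idx, ]
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(s$atoms)),
    ifelse(nchar(s$atoms$name) < 4, paste0(" ", s$atoms$name), s$atoms$name),
    " ", r$aa, r$chain, r$resno, ifelse(r$ins == "", " ", r$ins),
    s$atoms$x, s$atoms$y, s$atoms$z, s$atoms$occupancy, 0,
    s$atoms$element)
  txt <- paste(c(lines, "TER", "END"), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Classify a residue as buried or exposed
#'
#' Residues with relative solvent accessibility at or below 25% are
#' classified as buried, above as exposed.
#'
#' @param rsa numeric vector of relative solvent accessibilities in `[0,1]`.
#' @param threshold burial threshold, default 0.25.
#' @return character vector, `"buried"` or `"exposed"`.
#' @export
classify_exposure <- function(rsa, threshold = 0.25) {
  stopifnot(all(rsa >= 0 & rsa <= 1, na.rm = TRUE))
  ifelse(rsa <= threshold, "buried", "exposed")
}

#' Per-residue annotation table
#'
#' @param s an annotated `rin_structure`.
#' @param path optional path; when given, the table is written as TSV.
#' @return data.frame with chain, seq_id, aa, ss, asa, rsa.
#' @export
residue_table <- function(s, path = NULL) {
  out <- data.frame(
    chain = s$residues$chain,
    seq_id = paste0(s$residues$resno, s$residues$ins),
    aa = s$residues$aa,
    ss = s$residues$ss,
    asa = s$residues$asa,
    rsa = s$residues$rsa,
    stringsAsFactors = FALSE
  )
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Read a DSSP output file and override internal assignments
#'
#' Accepts the classic DSSP text format; the 8-state code is collapsed to
#' three states (H/G/I to H, E/B to E, everything else C).
#'
#' @param path DSSP output file.
#' @return data.frame with `chain`, `resno`, `ins`, `ss`, `rsa_abs`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) stop("format error: not a DSSP output file")
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 38 & substr(body, 14, 14) != "!"]
  ss8 <- substr(body, 17, 17)
  ss3 <- ifelse(ss8 %in% c("H", "G", "I"), "H",
                ifelse(ss8 %in% c("E", "B"), "E", "C"))
  data.frame(
    chain = substr(body, 12, 12),
    resno = as.integer(substr(body, 6, 10)),
    ins = trimws(substr(body, 11, 11)),
    ss = ss3,
    asa = suppressWarnings(as.numeric(substr(body, 35, 38))),
    stringsAsFactors = FALSE
  )
}

#' @describeIn read_dssp apply a DSSP table to a structure, overriding the
#'   internal secondary-structure and accessibility assignment.
#' @param s an `rin_structure`.
#' @param dssp data.frame from [read_dssp()].
#' @export
apply_dssp <- function(s, dssp) {
  key <- paste0(dssp$chain, "/", dssp$resno, dssp$ins)
  idx <- match(s$residues$key, key)
  if (anyNA(idx))
    stop("DSSP table does not cover residue ", s$residues$key[is.na(idx)][1])
  s$residues$ss <- dssp$ss[idx]
  s$residues$asa <- dssp$asa[idx]
  s$residues$rsa <- pmin(1, pmax(0, dssp$asa[idx] / MAX_ASA[s$residues$aa]))
  s
}
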