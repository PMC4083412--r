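## Workflow wrappers tying the modules together: network export, training
## with cross-validation, batch prediction, and the two-structure
## comparative scan. Each writes its outputs plus a config log sufficient
## to reproduce the run. A thin command-line front end over these
## functions ships in `inst/cli/rinstab.R`.

write_run_log <- function(out_dir, config) {
  lines <- vapply(names(config), function(k)
    paste0(k, "=", paste(format(config[[k]]), collapse = ",")), "")
  writeLines(lines, file.path(out_dir, "run_config.log"))
}

#' Export network and annotation tables for a structure
#'
#' @param pdb path to a PDB file.
#' @param chain chain identifier (default: first chain).
#' @param out_dir output directory (created if needed); receives
#'   `nodes.tsv`, `edges.tsv`, `residues.tsv` and `run_config.log`.
#' @param contact_cutoff generic-contact distance cutoff, Angstrom.
#' @return invisibly, the annotated structure.
#' @export
cmd_rin <- function(pdb, chain = NULL, out_dir = ".", contact_cutoff = 5.0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- annotate_structure(parse_pdb(pdb, chain))
  g <- build_rin(s, contact_cutoff = contact_cutoff)
  write_rin_tables(g, s, file.path(out_dir, "nodes.tsv"),
                   file.path(out_dir, "edges.tsv"))
  residue_table(s, file.path(out_dir, "residues.tsv"))
  write_run_log(out_dir, list(command = "rin", pdb = pdb, chain = s$chain,
                              contact_cutoff = contact_cutoff))
  invisible(s)
}

#' Train a stability model from structures and a mutation table
#'
#' Encodes the mutations, runs k-fold cross-validation, then trains a
#' final model on all rows and serializes it.
#'
#' @param mutations mutation data.frame (with `ddg`) or TSV path.
#' @param structures named list of `rin_structure`s, or a named character
#'   vector of PDB paths keyed by `pdb_id`.
#' @param variant feature variant: `"full"`, `"no_topology"`, `"minimal"`.
#' @param seed integer seed.
#' @param out_dir output directory: `model.json`, `cv_metrics.tsv`,
#'   `training_log.tsv`, `run_config.log`.
#' @param k cross-validation folds.
#' @param ... passed to [train_model()].
#' @return invisibly, list(model, cv).
#' @export
cmd_train <- function(mutations, structures, variant = "full", seed = 1L,
                      out_dir = ".", k = 10, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(mutations)) mutations <- read_mutation_table(mutations)
  if (!"ddg" %in% names(mutations) || all(is.na(mutations$ddg)))
    stop("mutation table has no ddg column to train on")
  if (is.character(structures))
    structures <- lapply(structures, parse_pdb)
  manifest <- variant_subset(default_manifest(), variant)
  X <- encode_table(mutations, structures, manifest = manifest)
  y <- mutations$ddg
  cv <- cross_validate(X, y, k = k, seed = seed, ...)
  model <- train_model(X, y, seed = seed, ...)
  save_model(model, file.path(out_dir, "model.json"))
  utils::write.table(cv$metrics, file.path(out_dir, "cv_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(model$history, file.path(out_dir, "training_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_log(out_dir, list(command = "train", variant = variant,
                              seed = seed, k = k, n = nrow(X)))
  invisible(list(model = model, cv = cv))
}

parse_mutation_token <- function(token) {
  m <- regmatches(token, regexec("^([A-Za-z])(\\d+[A-Za-z]?)([A-Za-z])$",
                                 token))[[1]]
  if (length(m) != 4)
    return(NULL)
  list(wt = toupper(m[2]), position = m[3], mut = toupper(m[4]))
}

#' Predict stability changes for a batch of mutations
#'
#' Mutations are given as tokens like `"A123G"` (wild-type, position with
#' optional insertion code, mutant). Per-row failures (unparsable token,
#' site not in the chain, wild-type mismatch) are reported in the output
#' table without aborting the batch.
#'
#' @param model_file path to a serialized model, or a `ddg_model`.
#' @param pdb PDB path or `rin_structure`.
#' @param chain chain identifier.
#' @param mutations character vector of mutation tokens.
#' @param ph,temp environment for all rows.
#' @param variant feature variant the model was trained on.
#' @param out optional TSV output path.
#' @return data.frame: mutation, predicted ddg, ss, rsa, exposure, error.
#' @export
cmd_predict <- function(model_file, pdb, chain = NULL, mutations,
                        ph = 7, temp = 25, variant = "full", out = NULL) {
  manifest <- variant_subset(default_manifest(), variant)
  model <- if (inherits(model_file, "ddg_model")) model_file
           else load_model(model_file, expected_hash = manifest_hash(manifest))
  s <- if (inherits(pdb, "rin_structure")) pdb else parse_pdb(pdb, chain)
  if (all(is.na(s$residues$ss))) s <- annotate_structure(s)
  g <- build_rin(s)
  evo <- suppressWarnings(evo_profile(s, NULL))
  pot <- potential_scores(s, g)
  cent <- lapply(subnetworks(g), node_centralities)
  rows <- lapply(mutations, function(tok) {
    base <- data.frame(mutation = tok, ddg = NA_real_, ss = NA_character_,
                       rsa = NA_real_, exposure = NA_character_,
                       error = "", stringsAsFactors = FALSE)
    rec <- parse_mutation_token(tok)
    if (is.null(rec)) { base$error <- "unparsable token"; return(base) }
    rec$ph <- ph; rec$temp <- temp
    v <- tryCatch(encode_mutation(rec, s, g, evo, pot, manifest, cent),
                  error = function(e) conditionMessage(e))
    if (is.character(v)) { base$error <- v; return(base) }
    i <- match(rec$position, paste0(s$residues$resno, s$residues$ins))
    base$ddg <- predict(model, matrix(v, 1, dimnames = list(NULL, names(v))))
    base$ss <- s$residues$ss[i]
    base$rsa <- s$residues$rsa[i]
    base$exposure <- classify_exposure(base$rsa)
    base
  })
  res <- do.call(rbind, rows)
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}

#' Comparative stability scan of two structures
#'
#' @param model_file serialized model path or `ddg_model`.
#' @param pdbA,pdbB PDB paths or structures (A = mesophile, B =
#'   thermophile by convention).
#' @param chainA,chainB chain identifiers.
#' @param phA,tempA,phB,tempB per-side environment.
#' @param out_dir output directory for `scan_sites.tsv` and
#'   `scan_summary.tsv`.
#' @param variant feature variant.
#' @return invisibly, the `scan_summary`.
#' @export
cmd_thermoscan <- function(model_file, pdbA, pdbB, chainA = NULL,
                           chainB = NULL, phA = 7, tempA = 25, phB = 7,
                           tempB = 65, out_dir = ".", variant = "full") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- variant_subset(default_manifest(), variant)
  model <- if (inherits(model_file, "ddg_model")) model_file
           else load_model(model_file, expected_hash = manifest_hash(manifest))
  sA <- if (inherits(pdbA, "rin_structure")) pdbA else parse_pdb(pdbA, chainA)
  sB <- if (inherits(pdbB, "rin_structure")) pdbB else parse_pdb(pdbB, chainB)
  sA <- annotate_structure(sA); sB <- annotate_structure(sB)
  aln <- needleman_wunsch(structure_sequence(sA), structure_sequence(sB))
  sc <- bidirectional_scan(sA, sB, aln, model,
                           envA = list(ph = phA, temp = tempA),
                           envB = list(ph = phB, temp = tempB),
                           manifest = manifest)
  utils::write.table(sc$sites, file.path(out_dir, "scan_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sc$totals, file.path(out_dir, "scan_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_log(out_dir, list(command = "thermoscan",
                              identity = sc_identity(aln),
                              phA = phA, tempA = tempA,
                              phB = phB, tempB = tempB))
  invisible(sc)
}

sc_identity <- function(aln) {
  sprintf("%d/%d", aln$identity_count, aln$alignment_length)
}
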