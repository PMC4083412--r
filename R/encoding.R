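## The fixed-width mutation descriptor. Every mutation is encoded as an
## ordered, named 184-slot vector: environment (pH, temperature), one-hot
## blocks for the wild-type, mutant and the two sequence neighbours,
## local context (3-state secondary structure + RSA), evolutionary
## features, potential terms, node centralities on the six per-bond-type
## subnetworks at three sequence positions, neighbour composition, and
## network size.

CENT_POSITIONS <- c("site", "left", "right")
CENT_MEASURES <- c("degree", "clustering", "closeness", "betweenness")

#' The default feature manifest
#'
#' Ordered table of the 184 descriptor slots with their group labels.
#' Groups and sizes: ENV (2), SEQ_ONEHOT (80), LOCAL (4), EVO (3),
#' POTENTIAL (2), NET_CENTRALITY (72 = 3 positions x 6 subnetworks x 4
#' measures), NET_COMPOSITION (20), NET_SIZE (1).
#'
#' @return data.frame with columns `slot`, `group`.
#' @export
default_manifest <- function() {
  cent <- character(0)
  for (pos in CENT_POSITIONS)
    for (net in c(EDGE_TYPES, "ALL"))
      for (m in CENT_MEASURES)
        cent <- c(cent, paste("net", pos, net, m, sep = "_"))
  slots <- c(
    "ph", "temp",
    paste0("wt_", AA3), paste0("mut_", AA3),
    paste0("left_", AA3), paste0("right_", AA3),
    "ss_H", "ss_E", "ss_C", "rsa",
    "conservation", "mi", "acp",
    "pot_pairwise", "pot_solvation",
    cent,
    paste0("comp_", AA3),
    "network_size"
  )
  groups <- c(
    rep("ENV", 2), rep("SEQ_ONEHOT", 80), rep("LOCAL", 4), rep("EVO", 3),
    rep("POTENTIAL", 2), rep("NET_CENTRALITY", 72),
    rep("NET_COMPOSITION", 20), rep("NET_SIZE", 1)
  )
  data.frame(slot = slots, group = groups, stringsAsFactors = FALSE)
}

#' One-hot encoding of a residue type
#'
#' @param aa three-letter (or one-letter) standard residue code.
#' @return numeric 20-vector named by three-letter code, exactly one 1.
#' @export
one_hot <- function(aa) {
  aa <- toupper(aa)
  if (nchar(aa) == 1) aa <- aa_one_to_three(aa)
  idx <- match(aa, AA3)
  if (is.na(idx)) stop("non-standard residue code: ", aa)
  v <- numeric(20)
  v[idx] <- 1
  stats::setNames(v, AA3)
}

#' Restrict a manifest to a model variant
#'
#' `"full"` keeps all 184 slots. `"no_topology"` drops the network
#' topology groups (centralities, composition, size), leaving 91 slots.
#' `"minimal"` keeps only environment, sequence one-hot, local context,
#' conservation, the potential terms and the network size (90 slots).
#'
#' @param manifest a manifest data.frame.
#' @param variant one of `"full"`, `"no_topology"`, `"minimal"`.
#' @return the restricted manifest.
#' @export
variant_subset <- function(manifest = default_manifest(),
                           variant = c("full", "no_topology", "minimal")) {
  variant <- match.arg(variant)
  switch(variant,
    full = manifest,
    no_topology = manifest[!manifest$group %in%
      c("NET_CENTRALITY", "NET_COMPOSITION", "NET_SIZE"), , drop = FALSE],
    minimal = manifest[manifest$group %in%
      c("ENV", "SEQ_ONEHOT", "LOCAL", "POTENTIAL", "NET_SIZE") |
      manifest$slot == "conservation", , drop = FALSE]
  )
}

#' Serialize / hash a manifest
#'
#' @param manifest a manifest data.frame.
#' @param path optional TSV output path.
#' @return for [write_manifest()], the path invisibly; for
#'   [manifest_hash()], a short hash string identifying the slot layout.
#' @export
write_manifest <- function(manifest, path) {
  out <- cbind(index = seq_len(nrow(manifest)), manifest)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
manifest_hash <- function(manifest) {
  digest::digest(paste(manifest$slot, collapse = "|"), algo = "xxhash32")
}

#' Encode one mutation as a feature vector
#'
#' @param m mutation record: list or one-row data.frame with `position`
#'   (author residue number, optionally with insertion code), `wt`,
#'   `mut` (one-letter codes), `ph`, `temp`.
#' @param s annotated `rin_structure` (ss and rsa assigned).
#' @param rin the structure's interaction network.
#' @param evo evolutionary profile from [evo_profile()].
#' @param pot potential scores from [potential_scores()].
#' @param manifest slot layout, default [default_manifest()].
#' @param centralities optional precomputed per-subnetwork centrality
#'   tables (list of data.frames from [node_centralities()]), to avoid
#'   recomputation when encoding many mutations on one structure.
#' @return named numeric vector aligned to the manifest.
#' @export
encode_mutation <- function(m, s, rin, evo, pot,
                            manifest = default_manifest(),
                            centralities = NULL) {
  pos_key <- as.character(m$position)
  i <- match(pos_key, paste0(s$residues$resno, s$residues$ins))
  if (is.na(i)) stop("mutation site not found: position ", pos_key)
  wt3 <- aa_one_to_three(m$wt)
  if (s$residues$aa[i] != wt3)
    stop("wild-type check failed at position ", pos_key, ": expected ",
         m$wt, ", structure has ", aa_three_to_one(s$residues$aa[i]))
  n <- nrow(s$residues)
  subs <- subnetworks(rin)
  if (is.null(centralities))
    centralities <- lapply(subs, node_centralities)

  vals <- c(ph = as.numeric(m$ph), temp = as.numeric(m$temp))
  block <- function(prefix, idx) {
    v <- if (is.na(idx)) stats::setNames(numeric(20), AA3)
         else one_hot(s$residues$aa[idx])
    stats::setNames(v, paste0(prefix, "_", AA3))
  }
  left <- if (i > 1) i - 1L else NA_integer_
  right <- if (i < n) i + 1L else NA_integer_
  vals <- c(vals,
            stats::setNames(one_hot(wt3), paste0("wt_", AA3)),
            stats::setNames(one_hot(m$mut), paste0("mut_", AA3)),
            block("left", left), block("right", right))
  ss <- s$residues$ss[i]
  if (is.na(ss)) stop("structure not annotated: run annotate_structure()")
  vals <- c(vals, ss_H = as.numeric(ss == "H"), ss_E = as.numeric(ss == "E"),
            ss_C = as.numeric(ss == "C"), rsa = s$residues$rsa[i])
  vals <- c(vals, conservation = evo$conservation[i], mi = evo$mi[i],
            acp = evo$acp[i],
            pot_pairwise = pot$pairwise[i], pot_solvation = pot$solvation[i])
  key_at <- function(idx) if (is.na(idx)) NA_character_ else s$residues$key[idx]
  for (pos in CENT_POSITIONS) {
    idx <- switch(pos, site = i, left = left, right = right)
    key <- key_at(idx)
    for (net in c(EDGE_TYPES, "ALL")) {
      ct <- centralities[[net]]
      row <- if (is.na(key)) NULL else ct[ct$key == key, , drop = FALSE]
      for (meas in CENT_MEASURES) {
        v <- if (is.null(row) || nrow(row) == 0) 0 else row[[meas]]
        vals[paste("net", pos, net, meas, sep = "_")] <- v
      }
    }
  }
  comp <- neighbor_composition(rin, s$residues$key[i])
  vals <- c(vals, stats::setNames(comp$composition, paste0("comp_", AA3)),
            network_size = comp$network_size)
  out <- vals[manifest$slot]
  names(out) <- manifest$slot
  if (any(!is.finite(out)))
    stop("non-finite feature: ", manifest$slot[which(!is.finite(out))[1]])
  out
}

#' Encode a mutation table into a feature matrix
#'
#' Structure-level work (annotation, network, centralities, profiles) is
#' done once per structure, then each mutation row is encoded.
#'
#' @param mutations data.frame with columns `pdb_id`, `chain`, `position`,
#'   `wt`, `mut`, `ph`, `temp` (and optionally `ddg`).
#' @param structures named list of annotated `rin_structure` objects,
#'   keyed by `pdb_id`.
#' @param msas optional named list of `rin_msa` objects keyed by `pdb_id`.
#' @param manifest slot layout.
#' @return numeric matrix, one row per mutation, columns = manifest slots.
#' @export
encode_table <- function(mutations, structures, msas = NULL,
                         manifest = default_manifest()) {
  ids <- unique(mutations$pdb_id)
  ctx <- list()
  for (id in ids) {
    s <- structures[[id]]
    if (is.null(s)) stop("no structure supplied for ", id)
    if (all(is.na(s$residues$ss))) s <- annotate_structure(s)
    g <- build_rin(s)
    msa <- if (!is.null(msas)) msas[[id]] else NULL
    evo <- if (is.null(msa)) suppressWarnings(evo_profile(s, NULL))
           else evo_profile(s, msa, g)
    pot <- potential_scores(s, g)
    ctx[[id]] <- list(s = s, g = g, evo = evo, pot = pot,
                      cent = lapply(subnetworks(g), node_centralities))
  }
  X <- matrix(NA_real_, nrow(mutations), nrow(manifest),
              dimnames = list(NULL, manifest$slot))
  for (k in seq_len(nrow(mutations))) {
    cc <- ctx[[mutations$pdb_id[k]]]
    X[k, ] <- encode_mutation(as.list(mutations[k, ]), cc$s, cc$g, cc$evo,
                              cc$pot, manifest, centralities = cc$cent)
  }
  X
}

#' Write a feature matrix as TSV
#'
#' @param X matrix from [encode_table()].
#' @param path output path.
#' @export
write_features <- function(X, path) {
  utils::write.table(as.data.frame(X), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
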