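## Mesophile/thermophile comparative workflow: globally align the two
## sequences, then predict the stability change of every aligned
## substitution in both directions (mesophile-to-thermophile on the
## mesophile structure, and vice versa), tallying predicted stability
## increases and decreases by burial class.

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties. A gap of
#' length L costs `gap_open + gap_extend * L`. Identity is counted over
#' the full alignment length, gap columns included in the denominator.
#'
#' @param seqA,seqB amino-acid sequences (one-letter strings).
#' @param substitution_matrix scoring matrix; default BLOSUM62.
#' @param gap_open,gap_extend affine gap parameters (positive costs),
#'   defaults 10 and 0.5.
#' @return object of class `pair_alignment`: gapped rows `alnA`/`alnB`,
#'   `score`, `identity_count`, `alignment_length`, `gap_count`, and
#'   `map` (data.frame posA, posB over gap-free columns).
#' @export
needleman_wunsch <- function(seqA, seqB, substitution_matrix = NULL,
                             gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence")
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (is.null(substitution_matrix)) {
    substitution_matrix <- get_blosum62()
  }
  alpha <- rownames(substitution_matrix)
  chars <- unique(strsplit(paste0(seqA, seqB), "")[[1]])
  bad <- setdiff(chars, alpha)
  if (length(bad)) stop("unknown letter(s): ", paste(bad, collapse = ", "))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(seqA), Biostrings::BString(seqB),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  a <- as.character(Biostrings::alignedPattern(aln))
  b <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  len <- length(ca)
  gap <- ca == "-" | cb == "-"
  posA <- cumsum(ca != "-"); posB <- cumsum(cb != "-")
  out <- list(alnA = a, alnB = b, score = Biostrings::score(aln),
              identity_count = sum(!gap & ca == cb),
              alignment_length = len,
              gap_count = sum(gap),
              map = data.frame(col = which(!gap), posA = posA[!gap],
                               posB = posB[!gap]))
  class(out) <- "pair_alignment"
  out
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("<pair_alignment> length %d, identity %d/%d (%.1f%%), gaps %d, score %.1f\n",
              x$alignment_length, x$identity_count, x$alignment_length,
              100 * x$identity_count / x$alignment_length, x$gap_count,
              x$score))
  invisible(x)
}

#' Bidirectional per-site stability scan
#'
#' For every aligned, gap-free, substituted column, predicts the
#' stability change of mutating structure A's residue to B's residue on
#' structure A (direction `AtoB`, e.g. mesophile-to-thermophile) under
#' A's pH/temperature, and the reverse on structure B (`BtoA`). Each
#' prediction is classified as a stability increase or decrease under the
#' positive-destabilizing convention (negative predicted value =
#' increase), and tallied by the mutated structure's burial class.
#'
#' @param structA,structB annotated `rin_structure` objects.
#' @param aln a [needleman_wunsch()] alignment of their sequences.
#' @param model a trained `ddg_model` (and matching `manifest`).
#' @param envA,envB lists with `ph` and `temp` per side.
#' @param manifest feature layout the model was trained on.
#' @return object of class `scan_summary`: `sites` (per-site data.frame)
#'   and `totals` (per-direction counts and energy sums).
#' @export
bidirectional_scan <- function(structA, structB, aln, model,
                               envA = list(ph = 7, temp = 25),
                               envB = list(ph = 7, temp = 65),
                               manifest = default_manifest()) {
  seqA <- strsplit(structure_sequence(structA), "")[[1]]
  seqB <- strsplit(structure_sequence(structB), "")[[1]]
  ca <- strsplit(aln$alnA, "")[[1]]; cb <- strsplit(aln$alnB, "")[[1]]
  m <- aln$map
  if (max(m$posA) > length(seqA) || max(m$posB) > length(seqB))
    stop("alignment does not map onto the structures")
  bad <- which(ca[m$col] != seqA[m$posA] | cb[m$col] != seqB[m$posB])
  if (length(bad))
    stop("alignment/sequence mismatch at alignment column ", m$col[bad[1]])
  sub <- m[seqA[m$posA] != seqB[m$posB], , drop = FALSE]

  prep <- function(s) {
    if (all(is.na(s$residues$ss))) s <- annotate_structure(s)
    g <- build_rin(s)
    list(s = s, g = g,
         evo = suppressWarnings(evo_profile(s, NULL)),
         pot = potential_scores(s, g),
         cent = lapply(subnetworks(g), node_centralities))
  }
  A <- prep(structA); B <- prep(structB)

  scan_dir <- function(from, to, posF, posT, env, direction) {
    rows <- list()
    for (k in seq_len(nrow(sub))) {
      i <- sub[[posF]][k]; j <- sub[[posT]][k]
      s <- from$s
      rec <- list(position = paste0(s$residues$resno[i], s$residues$ins[i]),
                  wt = aa_three_to_one(s$residues$aa[i]),
                  mut = aa_three_to_one(to$s$residues$aa[j]),
                  ph = env$ph, temp = env$temp)
      v <- tryCatch(encode_mutation(rec, s, from$g, from$evo, from$pot,
                                    manifest, centralities = from$cent),
                    error = function(e) NULL)
      if (is.null(v)) next  # unpredictable site (e.g. missing atoms)
      ddg <- predict(model, matrix(v, 1, dimnames = list(NULL, names(v))))
      rows[[length(rows) + 1L]] <- data.frame(
        direction = direction, col = sub$col[k],
        posA = sub$posA[k], posB = sub$posB[k],
        wt = rec$wt, mut = rec$mut, ddg = ddg,
        effect = if (ddg <= 0) "increase" else "decrease",
        exposure = classify_exposure(s$residues$rsa[i]),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  sites <- rbind(scan_dir(A, B, "posA", "posB", envA, "AtoB"),
                 scan_dir(B, A, "posB", "posA", envB, "BtoA"))
  totals <- do.call(rbind, lapply(c("AtoB", "BtoA"), function(d) {
    sel <- sites[sites$direction == d, , drop = FALSE]
    data.frame(direction = d,
               n_increase = sum(sel$effect == "increase"),
               n_decrease = sum(sel$effect == "decrease"),
               energy_sum = sum(sel$ddg),
               stringsAsFactors = FALSE)
  }))
  out <- list(sites = sites, totals = totals,
              n_substituted = nrow(sub))
  class(out) <- "scan_summary"
  out
}

#' @export
print.scan_summary <- function(x, ...) {
  print(x$totals)
  invisible(x)
}

#' Aggregate scan summaries into a hypothesis report
#'
#' One row per protein pair plus a totals row, mirroring the per-direction
#' increase/decrease counts and energy sums, and the percentage of
#' thermophile-to-mesophile substitutions predicted destabilizing
#' (overall and split by burial class) - the fraction supporting the
#' hypothesis that thermophilic variants are the stabilizing ones.
#' Directions with no substitutions report `NA` percentages.
#'
#' @param summaries named list of `scan_summary` objects (A = mesophile,
#'   B = thermophile).
#' @return list with `pairs` (per-pair table) and `support` (percentage
#'   summary for the BtoA, i.e. thermophile-to-mesophile, direction).
#' @export
hypothesis_report <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  nm <- names(summaries)
  if (is.null(nm)) nm <- paste0("pair", seq_along(summaries))
  rows <- lapply(seq_along(summaries), function(k) {
    tt <- summaries[[k]]$totals
    data.frame(pair = nm[k],
               MtoT_increase = tt$n_increase[tt$direction == "AtoB"],
               MtoT_decrease = tt$n_decrease[tt$direction == "AtoB"],
               MtoT_energy = tt$energy_sum[tt$direction == "AtoB"],
               TtoM_increase = tt$n_increase[tt$direction == "BtoA"],
               TtoM_decrease = tt$n_decrease[tt$direction == "BtoA"],
               TtoM_energy = tt$energy_sum[tt$direction == "BtoA"],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  totals <- data.frame(pair = "Total", t(colSums(pairs[, -1, drop = FALSE])))
  names(totals) <- names(pairs)
  pairs <- rbind(pairs, totals)

  all_sites <- do.call(rbind, lapply(summaries, function(s) s$sites))
  pct_decrease <- function(sel) {
    n <- sum(sel)
    if (n == 0) return(NA_real_)
    100 * sum(all_sites$effect[sel] == "decrease") / n
  }
  tm <- all_sites$direction == "BtoA"
  support <- data.frame(
    direction = "TtoM",
    pct_decrease_all = pct_decrease(tm),
    pct_decrease_exposed = pct_decrease(tm & all_sites$exposure == "exposed"),
    pct_decrease_buried = pct_decrease(tm & all_sites$exposure == "buried"))
  list(pairs = pairs, support = support)
}
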