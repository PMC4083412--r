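## Evolutionary features from a user-supplied multiple sequence alignment
## (conservation, mutual information, average cluster purity) and simple
## knowledge-based potential scores (pairwise contact + solvation) per
## residue. Alignment generation (e.g. PSI-BLAST) is outside the package:
## the MSA is an input.

#' Read a FASTA multiple sequence alignment
#'
#' @param path FASTA file with aligned (equal-length, gapped) rows.
#' @param query_id identifier of the row corresponding to the structure's
#'   sequence; defaults to the first row.
#' @return object of class `rin_msa`: list with `sequences` (character
#'   matrix rows x columns), `ids`, `query_row`, `n_rows`, `n_cols`.
#' @export
read_msa <- function(path, query_id = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 1) stop("format error: empty alignment")
  lens <- Biostrings::width(set)
  if (length(unique(lens)) != 1)
    stop("format error: ragged alignment (row lengths ",
         paste(unique(lens), collapse = ", "), ")")
  ids <- sub("\\s.*$", "", names(set))
  qr <- if (is.null(query_id)) 1L else match(query_id, ids)
  if (is.na(qr)) stop("query sequence not found: ", query_id)
  m <- do.call(rbind, strsplit(toupper(as.character(set)), ""))
  rownames(m) <- ids
  out <- list(sequences = m, ids = ids, query_row = qr,
              n_rows = nrow(m), n_cols = ncol(m))
  class(out) <- "rin_msa"
  out
}

msa_from_matrix <- function(m, query_row = 1L) {
  out <- list(sequences = m, ids = rownames(m), query_row = query_row,
              n_rows = nrow(m), n_cols = ncol(m))
  class(out) <- "rin_msa"
  out
}

#' Map structure positions to alignment columns
#'
#' Skips gaps in the query row; errors if the ungapped query sequence
#' does not match the structure sequence.
#'
#' @param msa an `rin_msa`.
#' @param s an `rin_structure`.
#' @return integer vector: alignment column per structure residue.
#' @export
msa_column_map <- function(msa, s) {
  q <- msa$sequences[msa$query_row, ]
  cols <- which(q != "-")
  sseq <- strsplit(structure_sequence(s), "")[[1]]
  if (length(cols) != length(sseq))
    stop("query/structure length mismatch: ", length(cols), " vs ",
         length(sseq))
  bad <- which(q[cols] != sseq)
  if (length(bad))
    stop("query/structure mismatch at structure position ", bad[1],
         ": alignment has ", q[cols[bad[1]]], ", structure has ",
         sseq[bad[1]])
  cols
}

column_freqs <- function(col) {
  col <- col[col %in% AA1]
  if (!length(col)) return(numeric(0))
  tab <- table(col)
  as.numeric(tab) / sum(tab)
}

#' Column conservation
#'
#' `1 - H / log2(20)` where `H` is the Shannon entropy of the amino-acid
#' frequencies in the column (gaps excluded). An all-gap column scores 0.
#'
#' @param msa an `rin_msa`.
#' @param col column index.
#' @return conservation in `[0,1]`.
#' @export
conservation <- function(msa, col) {
  p <- column_freqs(msa$sequences[, col])
  if (!length(p)) return(0)
  h <- -sum(p * log2(p))
  1 - h / log2(20)
}

#' Mutual information between two alignment columns
#'
#' Plug-in estimate over rows where both columns are ungapped; returns 0
#' when fewer than two such rows exist.
#'
#' @param msa an `rin_msa`.
#' @param i,j column indices.
#' @return MI in bits (>= 0 up to numerical noise).
#' @export
mutual_information <- function(msa, i, j) {
  a <- msa$sequences[, i]; b <- msa$sequences[, j]
  ok <- a %in% AA1 & b %in% AA1
  if (sum(ok) < 2) return(0)
  a <- a[ok]; b <- b[ok]
  pj <- table(a, b) / sum(ok)
  pa <- rowSums(pj); pb <- colSums(pj)
  idx <- pj > 0
  sum(pj[idx] * log2(pj[idx] / outer(pa, pb)[idx]))
}

#' Average cluster purity of a position
#'
#' For each contact partner column `j`, restrict the alignment to rows
#' carrying the query's residue at `i` and take the frequency of the most
#' common residue in column `j` among those rows; ACP is the mean over
#' partners. Partners default to the position's network neighbours (via
#' `contacts`), falling back to sequence neighbours when none are given.
#'
#' @param msa an `rin_msa`.
#' @param i column index of the position.
#' @param contacts integer vector of partner column indices, or `NULL`.
#' @return purity in `[0,1]` (1 when no usable partner exists).
#' @export
acp <- function(msa, i, contacts = NULL) {
  if (is.null(contacts) || !length(contacts))
    contacts <- intersect(c(i - 1L, i + 1L), seq_len(msa$n_cols))
  qa <- msa$sequences[msa$query_row, i]
  if (!qa %in% AA1) return(1)
  rows <- msa$sequences[, i] == qa
  pur <- vapply(contacts, function(j) {
    col <- msa$sequences[rows, j]
    p <- column_freqs(col)
    if (!length(p)) return(NA_real_)
    max(p)
  }, numeric(1))
  pur <- pur[is.finite(pur)]
  if (!length(pur)) return(1)
  mean(pur)
}

#' Evolutionary profile of a structure
#'
#' Per-residue conservation, mean mutual information with network
#' contacts, and average cluster purity. With `msa = NULL` the neutral
#' defaults (conservation 1, MI 0, ACP 1) are returned with a warning,
#' so prediction degrades gracefully when no alignment is available.
#'
#' @param s an `rin_structure`.
#' @param msa an `rin_msa` or `NULL`.
#' @param rin optional `rin`; when given, MI/ACP partners are the RIN
#'   neighbours of each position, otherwise sequence neighbours.
#' @return data.frame with conservation, mi, acp per residue.
#' @export
evo_profile <- function(s, msa = NULL, rin = NULL) {
  n <- nrow(s$residues)
  if (is.null(msa)) {
    warning("no MSA supplied; using neutral evolutionary features")
    return(data.frame(conservation = rep(1, n), mi = rep(0, n),
                      acp = rep(1, n)))
  }
  cmap <- msa_column_map(msa, s)
  partners <- function(i) {
    if (is.null(rin)) return(intersect(c(i - 1L, i + 1L), seq_len(n)))
    key <- s$residues$key[i]
    e <- rin$edges
    nb <- unique(c(e$v[e$u == key], e$u[e$v == key]))
    match(nb, s$residues$key)
  }
  cons <- vapply(cmap, function(cc) conservation(msa, cc), numeric(1))
  mi <- numeric(n); ac <- numeric(n)
  for (i in seq_len(n)) {
    pp <- partners(i)
    pp <- pp[!is.na(pp)]
    if (length(pp)) {
      mi[i] <- mean(vapply(cmap[pp], function(j)
        mutual_information(msa, cmap[i], j), numeric(1)))
      ac[i] <- acp(msa, cmap[i], cmap[pp])
    } else {
      mi[i] <- 0
      ac[i] <- acp(msa, cmap[i], NULL)
    }
  }
  data.frame(conservation = cons, mi = mi, acp = ac)
}

# -- knowledge-based potential scores ---------------------------------------

#' Reference contact and burial statistics from a structure ensemble
#'
#' Builds the observed/expected contact-frequency table and the burial
#' frequency table that parameterise [potential_scores()]. Pseudo-counts
#' keep every log-odds finite.
#'
#' @param structures list of annotated `rin_structure` objects.
#' @param pseudo pseudo-count added to every cell.
#' @return list with `contact` (20 x 20 observed/expected ratio),
#'   `burial` (per-aa P(buried | aa) / P(buried)) and `aa_freq`.
#' @export
reference_stats_from_structures <- function(structures, pseudo = 1) {
  cc <- matrix(pseudo, 20, 20, dimnames = list(AA3, AA3))
  buried_ct <- stats::setNames(rep(pseudo, 20), AA3)
  total_ct <- stats::setNames(rep(2 * pseudo, 20), AA3)
  for (s in structures) {
    if (all(is.na(s$residues$rsa))) s <- compute_rsa(s)
    g <- build_rin(s)
    if (nrow(g$edges)) {
      e <- g$edges[g$edges$etype == "IAC", , drop = FALSE]
      ua <- g$nodes$aa[match(e$u, g$nodes$key)]
      va <- g$nodes$aa[match(e$v, g$nodes$key)]
      for (k in seq_along(ua)) {
        cc[ua[k], va[k]] <- cc[ua[k], va[k]] + 1
        cc[va[k], ua[k]] <- cc[va[k], ua[k]] + 1
      }
    }
    b <- s$residues$rsa <= 0.25
    for (k in seq_len(nrow(s$residues))) {
      aa <- s$residues$aa[k]
      total_ct[aa] <- total_ct[aa] + 1
      if (isTRUE(b[k])) buried_ct[aa] <- buried_ct[aa] + 1
    }
  }
  f_obs <- cc / sum(cc)
  marg <- rowSums(f_obs)
  f_exp <- outer(marg, marg)
  list(contact = f_obs / f_exp,
       p_buried_given_aa = buried_ct / total_ct,
       p_buried = sum(buried_ct) / sum(total_ct),
       aa_freq = total_ct / sum(total_ct))
}

ref_stats_cache <- new.env(parent = emptyenv())

#' Default reference statistics
#'
#' Computed once per session from a small deterministic ensemble of
#' synthetic helix and hairpin structures with seeded random sequences.
#' These defaults make the potential terms well-defined everywhere;
#' users with genuine statistical-potential outputs should prefer
#' [load_external_scores()].
#'
#' @return see [reference_stats_from_structures()].
#' @export
default_reference_stats <- function() {
  if (!is.null(ref_stats_cache$default)) return(ref_stats_cache$default)
  ens <- c(
    lapply(1:6, function(i) compute_rsa(make_fixture_structure(
      "helix", 24, sequence = "random", seed = 100 + i))),
    lapply(1:6, function(i) compute_rsa(make_fixture_structure(
      "hairpin", 18, sequence = "random", seed = 200 + i)))
  )
  ref_stats_cache$default <- reference_stats_from_structures(ens)
  ref_stats_cache$default
}

#' Per-residue knowledge-based potential scores
#'
#' Two pseudo-energy terms per residue: `pairwise(i)` is the sum over the
#' residue's generic-contact neighbours of `-log(ratio(aa_i, aa_j))`
#' where `ratio` is the observed/expected contact frequency from the
#' reference table, and `solvation(i)` is
#' `-log(P(buried-state of i | aa_i) / P(buried-state of i))`.
#'
#' @param s an annotated `rin_structure` (RSA required).
#' @param rin optional prebuilt `rin` for `s`.
#' @param ref reference statistics, default [default_reference_stats()].
#' @return data.frame with `pairwise` and `solvation` per residue.
#' @export
potential_scores <- function(s, rin = NULL, ref = default_reference_stats()) {
  if (is.null(ref$contact) || is.null(ref$p_buried_given_aa))
    stop("missing reference table; use default_reference_stats()")
  if (all(is.na(s$residues$rsa))) stop("structure lacks RSA; run compute_rsa()")
  if (is.null(rin)) rin <- build_rin(s)
  n <- nrow(s$residues)
  pw <- numeric(n); sv <- numeric(n)
  e <- rin$edges[rin$edges$etype == "IAC", , drop = FALSE]
  for (i in seq_len(n)) {
    key <- s$residues$key[i]; aa <- s$residues$aa[i]
    nb <- c(e$v[e$u == key], e$u[e$v == key])
    if (length(nb)) {
      aaj <- rin$nodes$aa[match(nb, rin$nodes$key)]
      pw[i] <- sum(-log(ref$contact[aa, aaj]))
    }
    buried <- s$residues$rsa[i] <= 0.25
    # P(aa | state) / P(aa) == P(state | aa) / P(state) by Bayes' rule
    ratio <- if (buried) ref$p_buried_given_aa[aa] / ref$p_buried
             else (1 - ref$p_buried_given_aa[aa]) / (1 - ref$p_buried)
    sv[i] <- -log(max(ratio, 1e-8))
  }
  data.frame(pairwise = pw, solvation = sv)
}

#' Override potential scores from a file
#'
#' Reads a TSV of externally computed per-residue scores (e.g. genuine
#' statistical-potential outputs) with columns `position`, `name`,
#' `value`, where `name` is `pairwise` or `solvation`.
#'
#' @param path TSV file.
#' @param s the structure the scores refer to.
#' @return data.frame with `pairwise` and `solvation` per residue.
#' @export
load_external_scores <- function(path, s) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "name", "value")
  if (!all(need %in% names(d)))
    stop("format error: expected columns ", paste(need, collapse = ", "))
  n <- nrow(s$residues)
  out <- data.frame(pairwise = numeric(n), solvation = numeric(n))
  for (k in seq_len(nrow(d))) {
    i <- match(as.character(d$position[k]),
               paste0(s$residues$resno, s$residues$ins))
    if (is.na(i)) stop("unknown position in score file: ", d$position[k])
    if (!d$name[k] %in% c("pairwise", "solvation"))
      stop("unknown score name: ", d$name[k])
    out[i, d$name[k]] <- d$value[k]
  }
  out
}
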