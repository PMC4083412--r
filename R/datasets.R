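## Mutation-table I/O, curation filters in the style used for
## thermodynamic stability training sets, and the synthetic target
## generator for parameter-recovery experiments.

MUTATION_COLUMNS <- c("pdb_id", "chain", "position", "wt", "mut", "ph",
                      "temp")

#' Read a mutation table
#'
#' TSV with header columns `pdb_id`, `chain`, `position`, `wt`, `mut`,
#' `ph`, `temp` and optionally `ddg` (kcal/mol). Rows with identical keys
#' are collapsed by averaging `ddg` with a warning; rows where the
#' wild-type equals the mutant are rejected.
#'
#' @param path TSV file.
#' @return data.frame of typed mutation records with attribute
#'   `rejected` (data.frame key, rule) listing dropped rows.
#' @export
read_mutation_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(MUTATION_COLUMNS, names(d))
  if (length(missing))
    stop("format error: missing column(s) ", paste(missing, collapse = ", "))
  if (!"ddg" %in% names(d)) d$ddg <- NA_real_
  d$wt <- toupper(d$wt); d$mut <- toupper(d$mut)
  rejected <- data.frame(key = character(), rule = character(),
                         stringsAsFactors = FALSE)
  key <- paste(d$pdb_id, d$chain, d$position, d$wt, d$mut, d$ph, d$temp,
               sep = "|")
  self <- d$wt == d$mut
  if (any(self)) {
    rejected <- rbind(rejected, data.frame(key = key[self],
                                           rule = "wt equals mut"))
    d <- d[!self, , drop = FALSE]; key <- key[!self]
  }
  if (anyDuplicated(key)) {
    warning("duplicate mutation keys collapsed by averaging ddg")
    agg <- stats::aggregate(ddg ~ key, data = cbind(d, key = key),
                            FUN = mean, na.action = stats::na.pass)
    first <- d[match(agg$key, key), , drop = FALSE]
    first$ddg <- agg$ddg
    d <- first[order(match(agg$key, unique(key))), , drop = FALSE]
  }
  rownames(d) <- NULL
  attr(d, "rejected") <- rejected
  d
}

#' Apply stability-dataset curation filters
#'
#' Drops records involving proline (as wild-type or mutant) and records
#' destabilizing by more than `max_destab` kcal/mol under the configured
#' sign convention (the bound is one-sided: strong stabilizers are kept).
#' Each rejection is logged with the rule that fired.
#'
#' @param t mutation table (data.frame).
#' @param max_destab destabilization bound, kcal/mol, default 5.
#' @param exclude_proline drop proline records, default TRUE.
#' @param sign_convention `"positive_destabilizing"` (default) or
#'   `"negative_destabilizing"`.
#' @return the filtered table; attribute `rejection_log` is a data.frame
#'   (key, rule).
#' @export
apply_curation_filters <- function(t, max_destab = 5.0,
                                   exclude_proline = TRUE,
                                   sign_convention = "positive_destabilizing") {
  key <- paste(t$pdb_id, t$chain, t$position, t$wt, t$mut, sep = "|")
  log <- data.frame(key = character(), rule = character(),
                    stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(t))
  if (exclude_proline) {
    pro <- t$wt == "P" | t$mut == "P"
    if (any(pro))
      log <- rbind(log, data.frame(key = key[pro], rule = "proline"))
    drop <- drop | pro
  }
  destab <- if (sign_convention == "positive_destabilizing") t$ddg
            else -t$ddg
  far <- !is.na(destab) & destab > max_destab & !drop
  if (any(far))
    log <- rbind(log, data.frame(key = key[far], rule = "max_destab"))
  drop <- drop | far
  out <- t[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejection_log") <- log
  out
}

#' Simulate stability changes from a feature matrix
#'
#' `y = X %*% coefficients + N(0, noise_sd)` with seeded noise; the
#' parameter-recovery harness for the regressor.
#'
#' @param X feature matrix.
#' @param coefficients numeric vector, `ncol(X)` long.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return numeric vector of synthetic targets.
#' @export
simulate_ddg <- function(X, coefficients, noise_sd = 0.3, seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) != length(coefficients))
    stop("dimension mismatch: ", ncol(X), " columns vs ",
         length(coefficients), " coefficients")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  drop(X %*% coefficients) + stats::rnorm(nrow(X), 0, noise_sd)
}

#' Sample a synthetic mutation table over structures
#'
#' Draws random (site, mutant) pairs on the given structures with seeded
#' uniform pH in [5, 8] and temperature in [20, 40] degrees C: inputs for
#' desk-scale end-to-end runs of the encoder and regressor.
#'
#' @param structures named list of `rin_structure` objects.
#' @param n number of mutation records.
#' @param seed integer seed.
#' @return mutation data.frame (no `ddg` column).
#' @export
simulate_mutation_table <- function(structures, n, seed = 1L) {
  stopifnot(length(structures) >= 1, n >= 1)
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, function(s) s$pdb_id, "")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  ids <- sample(names(structures), n, replace = TRUE)
  rows <- lapply(seq_len(n), function(k) {
    s <- structures[[ids[k]]]
    i <- sample.int(nrow(s$residues), 1)
    wt <- aa_three_to_one(s$residues$aa[i])
    mut <- sample(setdiff(AA1, c(wt, "P")), 1)
    data.frame(pdb_id = ids[k], chain = s$chain,
               position = paste0(s$residues$resno[i], s$residues$ins[i]),
               wt = wt, mut = mut,
               ph = round(stats::runif(1, 5, 8), 2),
               temp = round(stats::runif(1, 20, 40), 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
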