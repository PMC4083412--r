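## Regression evaluation statistics for stability predictors: Pearson r,
## Spearman rho (Pearson on average ranks), Kendall tau (concordant minus
## discordant pairs over n(n-1)/2, ties counting in neither), the standard
## error sigma of the residuals, residual-based outlier trimming, and
## stratified reports by secondary structure and burial.

check_xy <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 2) stop("need at least 2 observations")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
}

#' Pearson correlation
#'
#' @param x experimental stability changes.
#' @param y predicted stability changes.
#' @return correlation in `[-1,1]`; 0 with a warning when either vector
#'   has zero variance.
#' @export
pearson <- function(x, y) {
  check_xy(x, y)
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    warning("zero variance; correlation undefined, returning 0")
    return(0)
  }
  sum(dx * dy) / sqrt(sx * sy)
}

#' Spearman rank correlation
#'
#' Pearson correlation applied to ranks, with average ranks for ties.
#'
#' @inheritParams pearson
#' @return rho in `[-1,1]`.
#' @export
spearman <- function(x, y) {
  check_xy(x, y)
  pearson(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

#' Kendall rank correlation
#'
#' `tau = (CP - DP) / (0.5 n (n - 1))` where CP and DP count the
#' concordant and discordant pairs; pairs tied in either vector count in
#' neither.
#'
#' @inheritParams pearson
#' @return tau in `[-1,1]`.
#' @export
kendall <- function(x, y) {
  check_xy(x, y)
  n <- length(x)
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  s <- sx * sy
  cp <- sum(s[upper.tri(s)] > 0)
  dp <- sum(s[upper.tri(s)] < 0)
  (cp - dp) / (0.5 * n * (n - 1))
}

#' Standard error of predictions
#'
#' `sigma = sqrt(sum((y - x)^2) / (n - 1))`: the root residual spread, in
#' kcal/mol. The denominator is configurable to `n`.
#'
#' @inheritParams pearson
#' @param denominator `"n-1"` (default) or `"n"`.
#' @return sigma >= 0.
#' @export
stderr_sigma <- function(x, y, denominator = c("n-1", "n")) {
  check_xy(x, y)
  denominator <- match.arg(denominator)
  n <- length(x)
  den <- if (denominator == "n-1") n - 1 else n
  sqrt(sum((y - x)^2) / den)
}

#' Residual-based outlier trimming
#'
#' Fits ordinary least squares `y ~ x` and drops the
#' `ceiling(fraction * n)` points with the largest absolute residuals.
#'
#' @inheritParams pearson
#' @param fraction fraction of points to drop, in `[0,1)`.
#' @return integer vector of retained indices.
#' @export
trim_outliers <- function(x, y, fraction = 0.10) {
  stopifnot(fraction >= 0, fraction < 1)
  check_xy(x, y)
  n <- length(x)
  n_drop <- ceiling(fraction * n)
  if (n_drop == 0) return(seq_len(n))
  fit <- stats::lm(y ~ x)
  res <- abs(stats::residuals(fit))
  keep <- order(res)[seq_len(n - n_drop)]
  sort(keep)
}

#' Full metrics report
#'
#' @inheritParams pearson
#' @return one-row data.frame: n, pearson_r, spearman_rho, kendall_tau,
#'   sigma.
#' @export
metrics_report <- function(x, y) {
  data.frame(n = length(x),
             pearson_r = pearson(x, y),
             spearman_rho = spearman(x, y),
             kendall_tau = kendall(x, y),
             sigma = stderr_sigma(x, y))
}

#' Stratified metrics report
#'
#' Metrics for the full set and for the secondary-structure (H/E/C) and
#' exposure (buried: RSA <= 25%; exposed otherwise) subsets. Strata with
#' fewer than 3 records are skipped with a warning.
#'
#' @param records data.frame with `ddg`, `ss` and `rsa` columns.
#' @param predictions numeric vector aligned to `records`.
#' @return data.frame of per-stratum metric rows with a `stratum` column.
#' @export
stratified_report <- function(records, predictions) {
  stopifnot(nrow(records) == length(predictions),
            all(c("ddg", "ss", "rsa") %in% names(records)))
  strata <- list(
    ALL = rep(TRUE, nrow(records)),
    H = records$ss == "H", E = records$ss == "E", C = records$ss == "C",
    buried = records$rsa <= 0.25, exposed = records$rsa > 0.25
  )
  rows <- list()
  for (nm in names(strata)) {
    sel <- which(strata[[nm]])
    if (length(sel) < 3) {
      warning("stratum ", nm, " skipped (n = ", length(sel), ")")
      next
    }
    r <- metrics_report(records$ddg[sel], predictions[sel])
    rows[[nm]] <- cbind(stratum = nm, r)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Intersect prediction tables on common mutations
#'
#' Restricts several prediction tables to the mutation keys
#' (`pdb_id`, `chain`, `position`, `wt`, `mut`) present in all of them,
#' the protocol used when comparing predictors that fail on different
#' subsets of a benchmark.
#'
#' @param tables list of data.frames carrying the key columns.
#' @return list of data.frames, each restricted to the common keys and
#'   ordered identically.
#' @export
common_mutations <- function(tables) {
  stopifnot(length(tables) >= 1)
  keyof <- function(d) paste(d$pdb_id, d$chain, d$position, d$wt, d$mut,
                             sep = "|")
  keys <- Reduce(intersect, lapply(tables, keyof))
  lapply(tables, function(d) {
    k <- keyof(d)
    d[match(keys, k), , drop = FALSE]
  })
}
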