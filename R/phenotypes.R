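# Feed-efficiency trait derivation and phenotype QC.

#' Derive feed-efficiency traits from per-animal test records
#'
#' Computes ADG = (end weight - onset weight) / days on test,
#' ADFI = total feed intake / days, and FCR = ADFI / ADG. Records with
#' non-positive gain are flagged (`ok = FALSE`) and excluded from FCR (and
#' later RFI); they are kept in the table.
#'
#' @param records data.frame with columns `id`, `on_bw` (kg), `end_bw`
#'   (kg), `days`, `intake` (total kg), and optionally `sex`, `pen`.
#' @return data.frame with the input columns plus `adg`, `adfi`, `fcr`,
#'   `ok`.
#' @export
derive_traits <- function(records) {
  req <- c("id", "on_bw", "end_bw", "days", "intake")
  if (!all(req %in% names(records)))
    hg_stop("records need columns: ", paste(req, collapse = ", "))
  if (any(records$days <= 0)) hg_stop("days on test must be > 0")
  if (any(records$on_bw <= 0 | records$end_bw <= 0))
    hg_stop("body weights must be > 0")
  out <- records
  out$adg <- (records$end_bw - records$on_bw) / records$days
  out$adfi <- records$intake / records$days
  out$ok <- out$adg > 0
  out$fcr <- ifelse(out$ok, out$adfi / out$adg, NA_real_)
  out
}

#' Residual feed intake
#'
#' RFI is the residual of the least-squares regression (with intercept) of
#' ADFI on onset body weight and ADG, so it averages zero by construction
#' within the cohort. Flagged records (`ok = FALSE`) and records with
#' missing regressors get `NA`.
#'
#' @param table output of [derive_traits()] (needs `adfi`, `on_bw`, `adg`).
#' @return `table` with an `rfi` column added.
#' @export
compute_rfi <- function(table) {
  use <- (table$ok %||% rep(TRUE, nrow(table))) &
    complete.cases(table[, c("adfi", "on_bw", "adg")])
  if (sum(use) < 3) hg_stop("need >= 3 complete records for RFI")
  d <- table[use, ]
  Xr <- cbind(1, d$on_bw, d$adg)
  if (qr(Xr)$rank < 3L)
    hg_stop("RFI regression error: collinear or constant regressors")
  fit <- lm.fit(Xr, d$adfi)
  table$rfi <- NA_real_
  table$rfi[use] <- fit$residuals
  table
}

#' Mean +/- k SD outlier mask
#'
#' Phenotype quality control: a value is retained iff it lies within `k`
#' standard deviations of the mean, both computed over the finite values.
#' When the SD is zero all finite values are retained. Non-finite entries
#' are always masked out.
#'
#' @param values numeric vector.
#' @param k SD multiplier (default 3).
#' @return Logical inclusion mask of the same length.
#' @export
qc_outliers <- function(values, k = 3) {
  fin <- is.finite(values)
  if (sum(fin) < 2) hg_stop("need >= 2 finite values")
  m <- mean(values[fin]); s <- sd(values[fin])
  if (s == 0) return(fin)
  fin & abs(values - m) <= k * s
}

#' Descriptive statistics for one trait
#'
#' Mirrors the usual trait-summary table: N, mean, SD (n-1 denominator),
#' CV% = 100 SD / mean (undefined when the mean is zero, as for a
#' zero-centred residual trait), max, min. Non-finite values are dropped.
#'
#' @param values numeric vector with at least two finite entries.
#' @return One-row data.frame with columns `n`, `mean`, `sd`, `cv`, `max`,
#'   `min`.
#' @export
descriptive_stats <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 2) hg_stop("need >= 2 finite values")
  m <- mean(x); s <- sd(x)
  cv <- if (m == 0) NA_real_ else 100 * s / m
  data.frame(n = length(x), mean = m, sd = s, cv = cv,
             max = max(x), min = min(x))
}

#' Pairwise Pearson correlations between traits
#'
#' @param table data.frame of phenotypes.
#' @param traits character vector of column names (default: the numeric
#'   columns).
#' @return List with matrices `r` and `p` (two-sided t-test) and `n`
#'   (complete pairs). Zero-variance traits give `NA` entries.
#' @export
trait_correlations <- function(table, traits = NULL) {
  if (is.null(traits))
    traits <- names(table)[vapply(table, is.numeric, logical(1))]
  k <- length(traits)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    x <- table[[traits[i]]]; y <- table[[traits[j]]]
    cc <- is.finite(x) & is.finite(y)
    nmat[i, j] <- nmat[j, i] <- sum(cc)
    if (sum(cc) < 3 || sd(x[cc]) == 0 || sd(y[cc]) == 0) next
    ct <- cor.test(x[cc], y[cc])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = nmat)
}

#' Shapiro-Wilk normality check (advisory)
#'
#' Thin wrapper reporting W and p; no transformation is applied either way.
#'
#' @param values numeric vector (3 to 5000 finite values).
#' @param alpha advisory threshold.
#' @return data.frame with `W`, `p`, and `normal` (p >= alpha).
#' @export
check_normality <- function(values, alpha = 0.05) {
  x <- values[is.finite(values)]
  st <- shapiro.test(x)
  data.frame(W = unname(st$statistic), p = st$p.value,
             normal = st$p.value >= alpha)
}
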