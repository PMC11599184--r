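# Multi-kernel REML variance-component estimation (average-information
# updates with an expectation-maximisation fallback), boundary-corrected
# likelihood-ratio tests, and the microbial-trait heritability screen.

# Restricted log-likelihood used throughout:
#   l_R = -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]
# with V = sum_i s2_i K_i + s2_e I and P the usual REML projection.

# Build the (augmented, intercept-first) covariate matrix, dropping aliased
# columns so X has full column rank.

#' Assemble a fixed-covariate design matrix
#'
#' Returns an intercept-first design matrix from any combination of factor
#' and numeric covariates, dropping aliased columns. Typical use mirrors
#' the study covariate set: sex, pen, onset body weight and the first three
#' genetic PCs.
#'
#' @param data data.frame (or NULL for intercept only).
#' @param columns character vector of columns of `data` to use; factors and
#'   characters are dummy-coded.
#' @param pcs optional numeric matrix of principal-component scores to
#'   append.
#' @return Numeric design matrix with full column rank (intercept first).
#' @export
make_covariates <- function(data = NULL, columns = NULL, pcs = NULL) {
  n <- if (!is.null(data)) nrow(data) else nrow(pcs)
  if (is.null(n)) hg_stop("cannot infer sample size for covariates")
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(data) && length(columns)) {
    for (cl in columns) {
      v <- data[[cl]]
      if (is.null(v)) hg_stop("covariate column not found: ", cl)
      if (is.character(v)) v <- factor(v)
      if (is.factor(v)) {
        mm <- model.matrix(~v)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cl, levels(v)[-1])
        X <- cbind(X, mm)
      } else X <- cbind(X, setNames(data.frame(v), cl))
    }
    X <- as.matrix(X)
  }
  if (!is.null(pcs)) X <- cbind(X, as.matrix(pcs))
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  X
}

# --- internal: generic dense REML -------------------------------------------

reml_eval <- function(sigma, Klist, X, y, nr) {
  n <- length(y); k <- length(Klist)
  V <- diag(sigma[k + 1], n)
  for (i in seq_len(k)) V <- V + sigma[i] * Klist[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  ldV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  ldX <- 2 * sum(log(diag(chx)))
  P <- Vi - ViX %*% chol2inv(chx) %*% t(ViX)
  Py <- drop(P %*% y)
  yPy <- sum(y * Py)
  ll <- -0.5 * (nr * log(2 * pi) + ldV + ldX + yPy)
  list(ll = ll, P = P, Py = Py)
}

reml_ai <- function(y, X, Klist, tol = 1e-8, max_iter = 200) {
  n <- length(y); p <- ncol(X); nr <- n - p; k <- length(Klist)
  ols <- lm.fit(X, y)
  vp <- sum(ols$residuals^2) / nr
  sigma <- rep(vp / (k + 1), k + 1)
  floor_ <- vp * 1e-6
  f <- reml_eval(sigma, Klist, X, y, nr)
  if (is.null(f)) hg_stop("REML: initial covariance not positive definite")
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    P <- f$P; Py <- f$Py
    w <- vector("list", k + 1)
    for (i in seq_len(k)) w[[i]] <- drop(Klist[[i]] %*% Py)
    w[[k + 1]] <- Py
    trPK <- numeric(k + 1)
    for (i in seq_len(k)) trPK[i] <- sum(P * Klist[[i]])
    trPK[k + 1] <- sum(diag(P))
    yPKPy <- vapply(w, function(v) sum(Py * v), 0)
    grad <- -0.5 * (trPK - yPKPy)

    # components pinned at the zero boundary with an inward-pointing
    # gradient are held fixed (active set) so the AI step cannot oscillate
    free <- !(sigma <= floor_ * 1.01 & grad < 0)
    if (!any(free)) { converged <- TRUE; break }
    dir <- numeric(k + 1)
    if (it == 1L) {
      dir[free] <- ((sigma^2 / nr) * 2 * grad)[free]     # EM warm-up
    } else {
      Pw <- lapply(w, function(v) drop(P %*% v))
      AI <- matrix(0, k + 1, k + 1)
      for (i in seq_len(k + 1)) for (j in i:(k + 1))
        AI[i, j] <- AI[j, i] <- 0.5 * sum(w[[i]] * Pw[[j]])
      dir[free] <- tryCatch(
        solve(AI[free, free, drop = FALSE], grad[free]),
        error = function(e) ((sigma^2 / nr) * 2 * grad)[free])
    }
    step_ok <- FALSE
    for (h in 0:12) {
      cand <- pmax(sigma + dir / 2^h, floor_)
      f2 <- reml_eval(cand, Klist, X, y, nr)
      if (!is.null(f2) && f2$ll >= f$ll - 1e-10) { step_ok <- TRUE; break }
    }
    if (!step_ok) {                                     # EM rescue step
      cand <- pmax(sigma + (sigma^2 / nr) * 2 * grad, floor_)
      f2 <- reml_eval(cand, Klist, X, y, nr)
      if (is.null(f2) || f2$ll < f$ll - 1e-8) { converged <- TRUE; break }
    }
    dll <- f2$ll - f$ll
    sigma <- cand; f <- f2
    if (abs(dll) < tol) { converged <- TRUE; break }
  }
  list(sigma = sigma, loglik = f$ll, converged = converged, iterations = it)
}

# --- internal: exact single-kernel REML via eigendecomposition --------------

reml_1k_eigen <- function(y, X, K) {
  n <- length(y); p <- ncol(X); nr <- n - p
  ee <- eigen(K, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  yt <- drop(crossprod(ee$vectors, y))
  Xt <- crossprod(ee$vectors, X)
  obj <- function(h) {
    d <- h * lam + (1 - h)
    if (any(d <= 0)) return(-Inf)
    w <- 1 / d
    XtWX <- crossprod(Xt, Xt * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, yt * w)))
    ss <- sum(w * (yt - drop(Xt %*% beta))^2)
    s2 <- ss / nr
    -0.5 * (nr * log(2 * pi) + nr * log(s2) + sum(log(d)) +
              2 * sum(log(diag(ch))) + nr)
  }
  grid <- seq(0, 1 - 1e-8, length.out = 21)
  vals <- vapply(grid, obj, 0)
  i0 <- which.max(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-10)
  h <- opt$maximum
  if (obj(0) >= opt$objective) { h <- 0; opt$objective <- obj(0) }
  d <- h * lam + (1 - h); w <- 1 / d
  XtWX <- crossprod(Xt, Xt * w)
  beta <- solve(XtWX, crossprod(Xt, yt * w))
  s2 <- sum(w * (yt - drop(Xt %*% beta))^2) / nr
  list(sigma = c(h * s2, (1 - h) * s2), loglik = opt$objective,
       converged = TRUE, iterations = NA_integer_)
}

reml_null <- function(y, X) {                 # residual-only model
  n <- length(y); p <- ncol(X); nr <- n - p
  fit <- lm.fit(X, y)
  s2 <- sum(fit$residuals^2) / nr
  ldx <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  ll <- -0.5 * (nr * log(2 * pi) + nr * log(s2) + ldx + nr)
  list(sigma = s2, loglik = ll, converged = TRUE, iterations = 0L)
}

#' Multi-kernel REML variance components
#'
#' Restricted maximum-likelihood estimation of the variance-component model
#' `y = X b + sum_i u_i + e`, `u_i ~ N(0, K_i s2_i)`, `e ~ N(0, I s2_e)`,
#' with non-negativity constraints. With one kernel the exact profiled
#' likelihood is maximised through an eigendecomposition; with two or three
#' kernels average-information updates with an EM warm-up/fallback are
#' iterated until successive restricted log-likelihoods differ by less than
#' `tol` (default 1e-8) or 200 iterations. Variance ratios are defined
#' against the sum of all fitted components.
#'
#' @param y numeric trait vector (complete cases only).
#' @param covariates design matrix from [make_covariates()], or `NULL` for
#'   intercept only.
#' @param kernels list of 0 to 3 kernels ([hg_kernel()] or matrices); an
#'   empty list fits the residual-only model (used as LRT reference).
#' @param tol,max_iter convergence controls.
#' @param use_eigen use the exact eigendecomposition path for single-kernel
#'   models (default). `FALSE` forces the iterative AI path (validation).
#' @return Object of class `hg_varcomp`: named `variances` and `ratios`
#'   (kernel components first, `residual` last), `loglik`, `converged`,
#'   `iterations`, `n`.
#' @export
fit_reml <- function(y, covariates = NULL, kernels = list(),
                     tol = 1e-8, max_iter = 200, use_eigen = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) hg_stop("y must be complete; subset to complete cases first")
  if (inherits(kernels, "hg_kernel") || is.matrix(kernels))
    kernels <- list(kernels)
  k <- length(kernels)
  if (k > 3) hg_stop("at most 3 kernels are supported")
  X <- covariates %||% matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (nrow(X) != n) hg_stop("covariates and y differ in length")
  if (qr(X)$rank < ncol(X)) hg_stop("singular covariate matrix")
  if (n <= ncol(X) + k) hg_stop("need n > #covariates + #kernels")
  Klist <- lapply(kernels, kernel_matrix)
  for (K in Klist) if (nrow(K) != n) hg_stop("kernel dimension mismatch")
  knames <- names(kernels)
  if (is.null(knames) || !all(nzchar(knames)))
    knames <- vapply(seq_len(k), function(i) {
      if (inherits(kernels[[i]], "hg_kernel")) kernels[[i]]$kind
      else paste0("k", i)
    }, "")
  knames <- make.unique(c(knames, "residual"))

  fit <- if (k == 0) reml_null(y, X)
  else if (k == 1 && use_eigen) reml_1k_eigen(y, X, Klist[[1]])
  else reml_ai(y, X, Klist, tol = tol, max_iter = max_iter)

  v <- setNames(fit$sigma, knames)
  structure(list(variances = v, ratios = v / sum(v), loglik = fit$loglik,
                 converged = fit$converged, iterations = fit$iterations,
                 n = n, n_covariates = ncol(X),
                 method = if (k == 0) "ols" else if (k == 1 && use_eigen)
                   "eigen" else "ai-reml"),
            class = "hg_varcomp")
}

#' Boundary-corrected variance-component p-value
#'
#' Likelihood-ratio statistic `2 (lR_full - lR_reduced)` referred to a
#' 50:50 mixture of a point mass at zero and chi-square(1), the standard
#' reference for a single variance component tested on its boundary. A
#' statistic of 0 gives p = 0.5; 2.706 gives p = 0.05.
#'
#' @param full,reduced `hg_varcomp` fits; `reduced` must be nested in
#'   `full` (one kernel removed, same covariates).
#' @return p-value in (0, 0.5]; statistics below -1e-6 are flagged with a
#'   warning (numerical error) and clipped to 0.
#' @export
component_pvalue <- function(full, reduced) {
  lr <- 2 * (full$loglik - reduced$loglik)
  if (lr < -1e-6)
    warning("negative LR statistic (", format(lr), "); clipped to 0")
  lr <- max(lr, 0)
  0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
}

#' SNP heritability from a single-GRM model
#'
#' Thin wrapper over [fit_reml()] with one kernel; `h2 = s2_g / s2_p` with
#' `s2_p` the sum of the fitted components, and an LRT p-value against the
#' residual-only model via [component_pvalue()].
#'
#' @inheritParams fit_reml
#' @param G genomic relationship kernel.
#' @return List with `h2`, `p`, `fit` (full model) and `fit0`.
#' @export
estimate_heritability <- function(y, covariates = NULL, G) {
  full <- fit_reml(y, covariates, list(genetic = G))
  null <- fit_reml(y, covariates, list())
  list(h2 = unname(full$ratios[1]), p = component_pvalue(full, null),
       fit = full, fit0 = null)
}

#' Microbiability from a single-MRM model
#'
#' Same machinery as [estimate_heritability()] with the microbial kernel in
#' place of the GRM: `m2 = s2_m / s2_p`.
#'
#' @inheritParams fit_reml
#' @param M microbial relationship kernel.
#' @return List with `m2`, `p`, `fit`, `fit0`.
#' @export
estimate_microbiability <- function(y, covariates = NULL, M) {
  full <- fit_reml(y, covariates, list(microbiome = M))
  null <- fit_reml(y, covariates, list())
  list(m2 = unname(full$ratios[1]), p = component_pvalue(full, null),
       fit = full, fit0 = null)
}

#' Joint variance partition with per-component tests
#'
#' Fits the full model with all supplied kernels and, for each kernel, the
#' reduced model with that kernel removed; reports per-component variances,
#' ratios and boundary-corrected LRT p-values (the layout of a joint
#' variance-partition table).
#'
#' @inheritParams fit_reml
#' @return data.frame with one row per component (including residual):
#'   `component`, `variance`, `ratio`, `p_value` (NA for the residual),
#'   plus attributes `loglik` and `converged`.
#' @export
variance_partition <- function(y, covariates = NULL, kernels,
                               tol = 1e-8, max_iter = 200) {
  full <- fit_reml(y, covariates, kernels, tol = tol, max_iter = max_iter)
  k <- length(kernels)
  pv <- rep(NA_real_, k + 1)
  for (i in seq_len(k)) {
    red <- fit_reml(y, covariates, kernels[-i], tol = tol,
                    max_iter = max_iter)
    pv[i] <- component_pvalue(full, red)
  }
  out <- data.frame(component = names(full$variances),
                    variance = unname(full$variances),
                    ratio = unname(full$ratios),
                    p_value = pv)
  attr(out, "loglik") <- full$loglik
  attr(out, "converged") <- full$converged
  out
}

#' Classify a microbial taxon by detection rate
#'
#' Detection above 60% gives a quantitative trait, 30-60% (inclusive)
#' binary, below 30% excluded.
#'
#' @param detection_rate fraction in `[0, 1]` (vectorised).
#' @return factor with levels `quantitative`, `binary`, `excluded`.
#' @export
classify_microbial_trait <- function(detection_rate) {
  if (any(detection_rate < 0 | detection_rate > 1))
    hg_stop("detection rate must be in [0, 1]")
  factor(ifelse(detection_rate > 0.60, "quantitative",
                ifelse(detection_rate >= 0.30, "binary", "excluded")),
         levels = c("quantitative", "binary", "excluded"))
}

# Encode a taxon as an analysable trait: standardised log(abundance + 1)
# for quantitative taxa, 0/1 presence for binary taxa.
encode_microbial_trait <- function(ab_col, mode) {
  if (mode == "quantitative") {
    v <- log(ab_col + 1)
    if (sd(v) == 0) return(NULL)
    as.numeric(scale(v))
  } else if (mode == "binary") {
    as.numeric(ab_col > 0)
  } else NULL
}

#' Per-genus heritability screen
#'
#' Classifies every taxon by detection rate, encodes quantitative taxa as
#' standardised log(abundance + 1) and binary taxa as 0/1 presence, and
#' fits the single-GRM model to each encoded trait. Excluded taxa (and taxa
#' whose fit fails) are not reported with estimates; failures are recorded
#' and the screen continues.
#'
#' @param ab samples x taxa relative-abundance matrix.
#' @param covariates design matrix (or NULL).
#' @param G genomic relationship kernel.
#' @param alpha significance level for the LRT (default 0.05).
#' @return data.frame: `taxon`, `detection`, `mode`, `h2`, `p`,
#'   `significant`, `error` (NA when the fit succeeded).
#' @export
genus_heritability_screen <- function(ab, covariates = NULL, G,
                                      alpha = 0.05) {
  ab <- as.matrix(ab)
  det <- detection_rates(ab)
  mode <- classify_microbial_trait(det)
  keep <- mode != "excluded"
  taxa <- colnames(ab) %||% paste0("taxon", seq_len(ncol(ab)))
  rows <- lapply(which(keep), function(j) {
    enc <- encode_microbial_trait(ab[, j], as.character(mode[j]))
    row <- data.frame(taxon = taxa[j], detection = det[j],
                      mode = as.character(mode[j]), h2 = NA_real_,
                      p = NA_real_, significant = FALSE,
                      error = NA_character_, stringsAsFactors = FALSE)
    if (is.null(enc)) { row$error <- "constant trait"; return(row) }
    res <- tryCatch({
      full <- fit_reml(enc, covariates, list(genetic = G))
      null <- fit_reml(enc, covariates, list())
      p <- component_pvalue(full, null)
      list(h2 = unname(full$ratios[1]), p = p)
    }, error = function(e) e)
    if (inherits(res, "error")) row$error <- conditionMessage(res)
    else {
      row$h2 <- res$h2; row$p <- res$p
      row$significant <- res$p < alpha
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
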