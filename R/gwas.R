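# Mixed-model association: per-SNP tests under a polygenic background,
# the empirical FDR threshold, per-genotype summaries, and the
# microbiome-GWAS driver.

#' Mixed-model GWAS
#'
#' Tests each SNP in the model `y = Q a + x b + g + e` with
#' `g ~ N(0, G s2_g)`. The default `"two-step"` mode estimates the
#' background variance components once on the null (no-SNP) model, rotates
#' the data by the eigenvectors of `G`, and tests every SNP by generalised
#' least squares under that fixed covariance (the EMMAX/P3D
#' approximation). `"exact"` mode re-maximises the restricted likelihood
#' over the variance ratio for every SNP (slow; used for validation).
#' Wald-type t statistics with `n - p - 1` residual degrees of freedom are
#' reported in both modes. SNPs collinear with the covariates get `NA`.
#'
#' @param y numeric trait vector.
#' @param covariates design matrix from [make_covariates()] or NULL
#'   (intercept only).
#' @param geno post-QC [hg_geno()] (no missing values) or allele-count
#'   matrix.
#' @param G background kernel; computed from `geno` when NULL.
#' @param method `"two-step"` (default) or `"exact"`.
#' @return Object of class `hg_gwas`: data.frame `snps` (snp, chr, pos,
#'   beta, se, stat, p, maf), `threshold` (from [fdr_threshold()]),
#'   `significant` (SNP IDs with p < threshold), `null_fit`, `method`.
#' @export
run_lmm_gwas <- function(y, covariates = NULL, geno, G = NULL,
                         method = c("two-step", "exact")) {
  method <- match.arg(method)
  g <- if (inherits(geno, "hg_geno")) geno else hg_geno(geno)
  S <- g$X
  if (anyNA(S)) hg_stop("GWAS requires post-QC (imputed) genotypes")
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(S) != n) hg_stop("genotypes and y differ in sample count")
  if (is.null(G)) G <- compute_grm(g)
  X <- covariates %||% matrix(1, n, 1)
  X <- as.matrix(X)

  null_fit <- fit_reml(y, X, list(genetic = G))
  s2g <- null_fit$variances[1]; s2e <- null_fit$variances[2]
  ee <- eigen(kernel_matrix(G), symmetric = TRUE)
  d <- pmax(ee$values, 0) * s2g + s2e
  sw <- 1 / sqrt(d)
  yt <- drop(crossprod(ee$vectors, y)) * sw
  Xt <- crossprod(ee$vectors, X) * sw
  St <- crossprod(ee$vectors, S) * sw

  p_cov <- ncol(X)
  df <- n - p_cov - 1
  freq <- colMeans(S) / 2
  maf <- pmin(freq, 1 - freq)

  if (method == "two-step") {
    qx <- qr(Xt)
    ry <- qr.resid(qx, yt)
    RS <- qr.resid(qx, St)
    sxx <- colSums(RS^2)
    sxy <- colSums(RS * ry)
    syy <- sum(ry^2)
    ok <- sxx > 1e-10
    beta <- ifelse(ok, sxy / sxx, NA_real_)
    rss <- syy - ifelse(ok, sxy^2 / sxx, 0)
    s2 <- rss / df
    se <- ifelse(ok, sqrt(s2 / sxx), NA_real_)
    stat <- beta / se
    pval <- 2 * pt(-abs(stat), df)
  } else {
    lam <- pmax(ee$values, 0)
    yt0 <- drop(crossprod(ee$vectors, y))
    Xt0 <- crossprod(ee$vectors, X)
    St0 <- crossprod(ee$vectors, S)
    nr <- n - p_cov - 1
    beta <- se <- stat <- pval <- rep(NA_real_, ncol(S))
    for (v in seq_len(ncol(S))) {
      Xv <- cbind(Xt0, St0[, v])
      if (qr(Xv)$rank <= p_cov) next
      obj <- function(h) {
        dd <- h * lam + (1 - h)
        w <- 1 / dd
        XtWX <- crossprod(Xv, Xv * w)
        ch <- tryCatch(chol(XtWX), error = function(e) NULL)
        if (is.null(ch)) return(-Inf)
        b <- backsolve(ch, forwardsolve(t(ch), crossprod(Xv, yt0 * w)))
        ss <- sum(w * (yt0 - drop(Xv %*% b))^2)
        -0.5 * (nr * log(2 * pi) + nr * log(ss / nr) + sum(log(dd)) +
                  2 * sum(log(diag(ch))) + nr)
      }
      gridv <- seq(0, 1 - 1e-8, length.out = 21)
      i0 <- which.max(vapply(gridv, obj, 0))
      opt <- optimize(obj, c(gridv[max(1, i0 - 1)],
                             gridv[min(21, i0 + 1)]),
                      maximum = TRUE, tol = 1e-9)
      h <- opt$maximum
      dd <- h * lam + (1 - h); w <- 1 / dd
      XtWX <- crossprod(Xv, Xv * w)
      XtWXi <- solve(XtWX)
      b <- drop(XtWXi %*% crossprod(Xv, yt0 * w))
      ss <- sum(w * (yt0 - drop(Xv %*% b))^2)
      s2 <- ss / nr
      j <- ncol(Xv)
      beta[v] <- b[j]
      se[v] <- sqrt(s2 * XtWXi[j, j])
      stat[v] <- beta[v] / se[v]
      pval[v] <- 2 * pt(-abs(stat[v]), nr)
    }
  }

  snps <- data.frame(snp = g$map$snp, chr = g$map$chr, pos = g$map$pos,
                     beta = beta, se = se, stat = stat, p = pval,
                     maf = maf, stringsAsFactors = FALSE)
  thr <- fdr_threshold(pval)
  sig <- snps$snp[!is.na(pval) & pval < thr]
  structure(list(snps = snps, threshold = thr, significant = sig,
                 n_p01 = sum(pval < 0.01, na.rm = TRUE),
                 null_fit = null_fit, method = method),
            class = "hg_gwas")
}

#' @export
print.hg_gwas <- function(x, ...) {
  cat(sprintf(
    "<hg_gwas:%s> %d SNPs, %d with p < 0.01, threshold %.3g, %d significant\n",
    x$method, nrow(x$snps), x$n_p01, x$threshold, length(x$significant)))
  invisible(x)
}

#' Empirical FDR significance threshold
#'
#' `P = 0.01 * n / i`, where `n` is the number of SNPs with p < 0.01 and
#' `i` the total number of eligible (tested) SNPs. A SNP is declared
#' significant iff its p-value is strictly below the threshold; with no
#' p-value below 0.01 the threshold is 0 and nothing is significant.
#'
#' @param pvalues numeric vector (NAs are not eligible).
#' @return The threshold (at most 0.01).
#' @export
fdr_threshold <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) hg_stop("no eligible p-values")
  0.01 * sum(p < 0.01) / length(p)
}

#' Per-genotype phenotype summary at one SNP
#'
#' Groups samples by genotype string (built from the SNP alleles), reports
#' group sizes, means and standard errors, and a one-way ANOVA F-test.
#' Empty genotype classes are omitted; singleton classes are reported
#' without an SE. A constant phenotype gives p = NA with a flag.
#'
#' @param counts allele counts (0/1/2) at the SNP.
#' @param y phenotype vector.
#' @param alleles length-2 character, the counted allele first.
#' @return List with `groups` (data.frame genotype, n, mean, se) and
#'   `p_anova`.
#' @export
genotype_group_summary <- function(counts, y, alleles = c("A", "B")) {
  ok <- !is.na(counts) & is.finite(y)
  counts <- counts[ok]; y <- y[ok]
  lab <- c(paste0(alleles[2], alleles[2]),
           paste0(alleles[1], alleles[2]),
           paste0(alleles[1], alleles[1]))[counts + 1]
  if (length(unique(lab)) < 2)
    hg_stop("SNP needs >= 2 observed genotype classes")
  grp <- split(y, factor(lab, levels = unique(lab[order(counts)])))
  groups <- data.frame(
    genotype = names(grp),
    n = vapply(grp, length, 0L),
    mean = vapply(grp, mean, 0),
    se = vapply(grp, function(v)
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  p <- if (sd(y) == 0) NA_real_ else {
    ft <- anova(lm(y ~ factor(lab)))
    ft$`Pr(>F)`[1]
  }
  list(groups = groups, p_anova = p,
       flag = if (sd(y) == 0) "constant phenotype" else NA_character_)
}

#' Microbiome GWAS over heritable taxa
#'
#' Runs [run_lmm_gwas()] on each encoded microbial trait (standardised
#' log(abundance + 1) for quantitative taxa, 0/1 presence for binary) with
#' a per-taxon [fdr_threshold()]. Intended input is the significant subset
#' of [genus_heritability_screen()]. Per-taxon failures are logged and the
#' scan continues.
#'
#' @param ab samples x taxa relative-abundance matrix.
#' @param covariates design matrix or NULL.
#' @param geno post-QC genotypes.
#' @param G background kernel (computed from `geno` when NULL).
#' @param taxa data.frame with columns `taxon` and `mode` (e.g. the
#'   significant rows of the heritability screen), or a character vector of
#'   taxon names (modes then derived from detection rates).
#' @return List with `results` (named list of `hg_gwas`), `summary`
#'   (data.frame: taxon, mode, threshold, n_significant), `significant`
#'   (data.frame of significant SNPs with taxon and MAF), `errors`.
#' @export
run_mbgwas <- function(ab, covariates = NULL, geno, G = NULL, taxa) {
  ab <- as.matrix(ab)
  if (is.character(taxa)) {
    det <- detection_rates(ab[, taxa, drop = FALSE])
    taxa <- data.frame(taxon = taxa,
                       mode = as.character(classify_microbial_trait(det)),
                       stringsAsFactors = FALSE)
  }
  g <- if (inherits(geno, "hg_geno")) geno else hg_geno(geno)
  if (is.null(G)) G <- compute_grm(g)
  results <- list(); errors <- character()
  for (i in seq_len(nrow(taxa))) {
    tx <- taxa$taxon[i]
    enc <- encode_microbial_trait(ab[, tx], taxa$mode[i])
    if (is.null(enc)) { errors[tx] <- "unencodable trait"; next }
    res <- tryCatch(run_lmm_gwas(enc, covariates, g, G),
                    error = function(e) e)
    if (inherits(res, "error")) errors[tx] <- conditionMessage(res)
    else results[[tx]] <- res
  }
  summ <- do.call(rbind, lapply(names(results), function(tx) {
    r <- results[[tx]]
    data.frame(taxon = tx,
               mode = taxa$mode[match(tx, taxa$taxon)],
               threshold = r$threshold,
               n_significant = length(r$significant),
               stringsAsFactors = FALSE)
  }))
  sig <- do.call(rbind, lapply(names(results), function(tx) {
    r <- results[[tx]]
    s <- r$snps[!is.na(r$snps$p) & r$snps$p < r$threshold, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    cbind(taxon = tx, s)
  }))
  list(results = results, summary = summ, significant = sig,
       errors = errors)
}
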