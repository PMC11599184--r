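# Genotype QC, relationship kernels (GRM, MRM, Hadamard interaction) and
# genetic principal components.

#' Genotype quality control
#'
#' Filters in the fixed order: SNP call rate, then minor allele frequency,
#' then individual call rate (on the surviving SNPs). Remaining missing
#' values are mean-imputed per SNP and SNPs that end up monomorphic are
#' removed.
#'
#' @param geno an [hg_geno()] object or allele-count matrix.
#' @param snp_call_rate,maf_min,ind_call_rate thresholds; SNPs/individuals
#'   are kept when strictly above the call-rate thresholds and when
#'   MAF is strictly above `maf_min`.
#' @return A filtered, fully imputed [hg_geno()]; QC counts are recorded in
#'   `attr(, "qc")`.
#' @export
qc_genotypes <- function(geno, snp_call_rate = 0.95, maf_min = 0.01,
                         ind_call_rate = 0.95) {
  g <- if (inherits(geno, "hg_geno")) geno else hg_geno(geno)
  X <- g$X; map <- g$map
  n0 <- nrow(X); s0 <- ncol(X)

  keep_snp <- colMeans(!is.na(X)) > snp_call_rate
  X <- X[, keep_snp, drop = FALSE]; map <- map[keep_snp, , drop = FALSE]

  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_maf <- !is.na(maf) & maf > maf_min
  X <- X[, keep_maf, drop = FALSE]; map <- map[keep_maf, , drop = FALSE]
  if (ncol(X) == 0) hg_stop("empty panel: all SNPs removed by QC")

  keep_ind <- rowMeans(!is.na(X)) > ind_call_rate
  X <- X[keep_ind, , drop = FALSE]

  if (anyNA(X)) {                         # per-SNP mean imputation
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  p2 <- colMeans(X) / 2
  poly <- p2 > 0 & p2 < 1
  X <- X[, poly, drop = FALSE]; map <- map[poly, , drop = FALSE]
  if (ncol(X) == 0) hg_stop("empty panel: all SNPs removed by QC")

  out <- hg_geno(X, map)
  attr(out, "qc") <- list(n_in = n0, s_in = s0, n_out = nrow(X),
                          s_out = ncol(X),
                          removed_call = s0 - sum(keep_snp),
                          removed_maf = sum(keep_snp) - sum(keep_maf))
  out
}

#' Genomic relationship matrix
#'
#' VanRaden-style GRM with per-SNP scaling:
#' \deqn{g_{ij} = \frac{1}{N}\sum_v
#'   \frac{(x_{iv}-2\bar p_v)(x_{jv}-2\bar p_v)}{2\bar p_v(1-\bar p_v)}}
#' where \eqn{\bar p_v} is the sample reference-allele frequency and N the
#' number of SNPs. Inputs must be complete (post-QC) and polymorphic.
#'
#' @param geno an [hg_geno()] or complete allele-count matrix.
#' @return [hg_kernel()] of kind `"GRM"`.
#' @export
compute_grm <- function(geno) {
  X <- if (inherits(geno, "hg_geno")) geno$X else as.matrix(geno)
  if (anyNA(X)) hg_stop("GRM requires a complete (imputed) matrix")
  p <- colMeans(X) / 2
  if (any(p <= 0 | p >= 1))
    hg_stop("division by zero: monomorphic SNP reached the GRM formula")
  W <- sweep(X, 2, 2 * p)
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(W) / ncol(X)
  hg_kernel(G, kind = "GRM", ids = rownames(X),
            meta = list(n_snps = ncol(X)))
}

#' Microbial relationship matrix
#'
#' Log-standardised kernel `M = X X' / p`: a pseudo-value of 1 is added to
#' each relative abundance, columns of the (natural) log table are
#' standardised to mean 0 and sample SD 1 (n-1 denominator), and `p` is the
#' number of retained taxa. Taxa that are constant across samples carry no
#' information and are dropped with a warning. The construction implies the
#' identity `trace(M)/n = (n-1)/n`.
#'
#' @param ab samples x taxa relative-abundance matrix (values >= 0).
#' @param pseudo_on one of `"relative"` (default; +1 on relative
#'   abundances, the literal reading of the construction) or `"counts"`
#'   (+1 on `ab` interpreted as counts -- identical arithmetic, provided for
#'   tables that arrive as counts).
#' @return [hg_kernel()] of kind `"MRM"`.
#' @export
compute_mrm <- function(ab, pseudo_on = c("relative", "counts")) {
  pseudo_on <- match.arg(pseudo_on)
  ab <- as.matrix(ab)
  if (nrow(ab) < 2) hg_stop("MRM needs >= 2 samples")
  if (any(!is.finite(ab)) || any(ab < 0))
    hg_stop("abundances must be finite and >= 0")
  L <- log(ab + 1)
  sds <- apply(L, 2, sd)
  keep <- sds > 0
  if (!any(keep)) hg_stop("all taxa constant across samples")
  if (any(!keep))
    warning(sum(!keep), " zero-variance taxa dropped from MRM")
  Xs <- scale(L[, keep, drop = FALSE])
  p <- sum(keep)
  M <- tcrossprod(Xs) / p
  hg_kernel(M, kind = "MRM", ids = rownames(ab),
            meta = list(n_taxa = p, pseudo_on = pseudo_on))
}

#' Genotype-by-microbiome interaction kernel
#'
#' Elementwise (Hadamard) product of the GRM and MRM; by the Schur product
#' theorem it is PSD whenever both factors are. Unnormalised by default.
#'
#' @param G,M kernels with identical sample IDs in the same order.
#' @param normalize if `TRUE`, rescale so the mean diagonal is 1.
#' @return [hg_kernel()] of kind `"interaction"`.
#' @export
compute_interaction_kernel <- function(G, M, normalize = FALSE) {
  Gm <- kernel_matrix(G); Mm <- kernel_matrix(M)
  gi <- kernel_ids(G); mi <- kernel_ids(M)
  if (!identical(dim(Gm), dim(Mm)) ||
      (!is.null(gi) && !is.null(mi) && !identical(gi, mi)))
    hg_stop("alignment error: G and M must share sample IDs and order")
  A <- Gm * Mm
  if (normalize) A <- A / mean(diag(A))
  hg_kernel(A, kind = "interaction", ids = gi,
            meta = list(normalized = normalize))
}

#' Genetic principal components
#'
#' Top-k eigenvectors of the kernel scaled by the square roots of their
#' eigenvalues. Sign convention: the largest-magnitude loading of each
#' component is positive. When the eigenvalue spectrum is (numerically)
#' flat the scores carry no population structure and the result is flagged
#' non-informative.
#'
#' @param G symmetric kernel.
#' @param k number of components (default 3).
#' @return n x k score matrix with attributes `eigenvalues` and
#'   `informative`.
#' @export
compute_pcs <- function(G, k = 3) {
  Gm <- kernel_matrix(G)
  n <- nrow(Gm)
  if (k > n) hg_stop("k must not exceed the number of samples")
  ee <- eigen(Gm, symmetric = TRUE)
  lam <- pmax(ee$values[seq_len(k)], 0)
  U <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i0 <- which.max(abs(U[, j]))
    if (U[i0, j] < 0) U[, j] <- -U[, j]
  }
  scores <- U %*% diag(sqrt(lam), k)
  dimnames(scores) <- list(kernel_ids(G), paste0("PC", seq_len(k)))
  spread <- diff(range(ee$values))
  attr(scores, "eigenvalues") <- ee$values
  attr(scores, "informative") <- spread > 1e-8 * max(abs(ee$values), 1e-300)
  scores
}
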