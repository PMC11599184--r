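# Lightweight S3 containers shared across modules.

#' Construct a genotype matrix object
#'
#' Holds an `n x s` allele-count matrix (values 0/1/2, `NA` allowed) together
#' with SNP metadata. Rows are samples, columns SNPs.
#'
#' @param X numeric matrix of allele counts; `rownames` are sample IDs and
#'   `colnames` SNP IDs (generated when absent).
#' @param map optional `data.frame` with columns `snp`, `chr`, `pos`, `a1`,
#'   `a2` (one row per SNP, in column order of `X`).
#' @return An object of class `hg_geno` with elements `X` and `map`.
#' @export
hg_geno <- function(X, map = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); s <- ncol(X)
  if (n < 1L || s < 1L) hg_stop("genotype matrix must be non-empty")
  bad <- X[!is.na(X)]
  if (length(bad) && (any(bad < 0) || any(bad > 2)))
    hg_stop("allele counts must lie in {0, 1, 2}")
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%04d", seq_len(n))
  if (is.null(colnames(X))) colnames(X) <- sprintf("snp%05d", seq_len(s))
  if (is.null(map)) {
    map <- data.frame(snp = colnames(X),
                      chr = rep_len(1:18, s),
                      pos = 10000L * (seq_len(s)),
                      a1 = "A", a2 = "B",
                      stringsAsFactors = FALSE)
  }
  if (nrow(map) != s) hg_stop("map must have one row per SNP")
  if (anyDuplicated(map$snp)) hg_stop("SNP IDs must be unique")
  if (any(map$pos < 0)) hg_stop("SNP positions must be non-negative")
  structure(list(X = X, map = map), class = "hg_geno")
}

#' @export
print.hg_geno <- function(x, ...) {
  cat(sprintf("<hg_geno> %d samples x %d SNPs, %.2f%% missing\n",
              nrow(x$X), ncol(x$X), 100 * mean(is.na(x$X))))
  invisible(x)
}

#' @export
dim.hg_geno <- function(x) dim(x$X)

#' Construct a relationship kernel
#'
#' An `n x n` symmetric similarity matrix with sample IDs and a provenance
#' tag (`"GRM"`, `"MRM"`, `"interaction"`, or free-form for simulated
#' kernels).
#'
#' @param K symmetric numeric matrix (asymmetry beyond 1e-10 is an error;
#'   below that it is symmetrised).
#' @param kind character tag recording how the kernel was built.
#' @param ids sample IDs; defaults to `rownames(K)`.
#' @param meta named list of construction metadata (marker/taxon counts,
#'   options).
#' @return Object of class `hg_kernel` with elements `K`, `ids`, `kind`,
#'   `meta`.
#' @export
hg_kernel <- function(K, kind = "kernel", ids = rownames(K), meta = list()) {
  if (!is.matrix(K)) K <- as.matrix(K)
  if (nrow(K) != ncol(K)) hg_stop("kernel must be square")
  if (!all(is.finite(K))) hg_stop("kernel entries must be finite")
  if (max(abs(K - t(K))) > 1e-10) hg_stop("kernel not symmetric within 1e-10")
  K <- (K + t(K)) / 2
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(K)))
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, ids = ids, kind = kind, meta = meta),
            class = "hg_kernel")
}

#' @export
print.hg_kernel <- function(x, ...) {
  cat(sprintf("<hg_kernel:%s> %d x %d, mean diag %.4f\n",
              x$kind, nrow(x$K), ncol(x$K), mean(diag(x$K))))
  invisible(x)
}

#' @export
as.matrix.hg_kernel <- function(x, ...) x$K

# Accept a kernel object or a bare matrix anywhere a kernel is needed.
kernel_matrix <- function(K) {
  if (inherits(K, "hg_kernel")) return(K$K)
  if (is.matrix(K)) return(K)
  hg_stop("expected an hg_kernel or a matrix")
}

kernel_ids <- function(K) {
  if (inherits(K, "hg_kernel")) K$ids else rownames(kernel_matrix(K))
}

#' @export
print.hg_varcomp <- function(x, ...) {
  cat(sprintf("<hg_varcomp> n = %d, %s after %s iterations, logLik = %.4f\n",
              x$n, if (x$converged) "converged" else "NOT converged",
              as.character(x$iterations), x$loglik))
  print(data.frame(variance = x$variances, ratio = x$ratios))
  invisible(x)
}

# Per-taxon detection rate: fraction of samples with abundance > 0.
#' Detection rates of an abundance table
#'
#' @param ab samples x taxa relative-abundance matrix.
#' @return Named numeric vector, fraction of samples with value > 0 per
#'   taxon.
#' @export
detection_rates <- function(ab) {
  ab <- as.matrix(ab)
  colMeans(ab > 0)
}
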