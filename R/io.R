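# File formats: TSV genotype/abundance/phenotype tables, PLINK
# .bed/.bim/.fam, kernels as TSV or packed doubles with a JSON sidecar.

#' Read / write a genotype table as TSV
#'
#' Layout: samples in rows (first column `id`), SNPs in columns; values
#' 0/1/2 or NA. A `<file>.map` TSV with columns snp/chr/pos/a1/a2 is
#' written alongside and read back when present.
#'
#' @param geno an [hg_geno()] object.
#' @param path file path.
#' @return `read_genotypes_tsv` returns an [hg_geno()].
#' @export
write_genotypes_tsv <- function(geno, path) {
  d <- data.frame(id = rownames(geno$X), geno$X, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(geno$map, paste0(path, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  X <- as.matrix(d[, -1, drop = FALSE])
  rownames(X) <- d$id
  mode(X) <- "double"
  mp <- paste0(path, ".map")
  map <- if (file.exists(mp))
    read.table(mp, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  else NULL
  hg_geno(X, map)
}

# PLINK 1 binary: SNP-major .bed, 2-bit codes per genotype
# (00 = 2 copies of A1, 10 = 1 copy, 11 = 0 copies, 01 = missing).

#' Write / read PLINK .bed/.bim/.fam
#'
#' Minimal SNP-major PLINK 1 binary support. The stored allele count is
#' the A1 (first allele) dosage.
#'
#' @param geno an [hg_geno()].
#' @param prefix path prefix (files `<prefix>.bed/.bim/.fam`).
#' @return `read_plink` returns an [hg_geno()].
#' @export
write_plink <- function(geno, prefix) {
  X <- geno$X; map <- geno$map
  n <- nrow(X)
  fam <- data.frame(fid = rownames(X), iid = rownames(X), pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = map$chr, snp = map$snp, cm = 0, pos = map$pos,
                    a1 = map$a1, a2 = map$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  code <- c(`0` = 3L, `1` = 2L, `2` = 0L)          # dosage -> 2-bit code
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  nb <- ceiling(n / 4)
  for (v in seq_len(ncol(X))) {
    g <- X[, v]
    cd <- ifelse(is.na(g), 1L, code[as.character(g)])
    cd <- c(cd, rep(0L, 4 * nb - n))
    m <- matrix(cd, nrow = 4)
    bytes <- m[1, ] + m[2, ] * 4L + m[3, ] * 16L + m[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  fam <- read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  names(bim) <- c("chr", "snp", "cm", "pos", "a1", "a2")
  n <- nrow(fam); s <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * s)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    hg_stop("not a SNP-major PLINK .bed file")
  body <- as.integer(raw[-(1:3)])
  nb <- ceiling(n / 4)
  dose <- c(2, NA, 1, 0)                            # 2-bit code -> dosage
  X <- matrix(NA_real_, n, s)
  shift <- c(1L, 4L, 16L, 64L)
  for (v in seq_len(s)) {
    bytes <- body[((v - 1) * nb + 1):(v * nb)]
    codes <- integer(4 * nb)
    for (k in 1:4)
      codes[seq(k, by = 4, length.out = nb)] <- (bytes %/% shift[k]) %% 4L
    X[, v] <- dose[codes[seq_len(n)] + 1L]
  }
  rownames(X) <- fam$V2
  colnames(X) <- bim$snp
  hg_geno(X, bim[, c("snp", "chr", "pos", "a1", "a2")])
}

#' Kernel I/O
#'
#' TSV format: square matrix with sample IDs as header and first column;
#' kind and metadata live in a `<file>.json` sidecar. The binary format
#' packs row-major doubles with the same sidecar.
#'
#' @param kernel an [hg_kernel()].
#' @param path file path.
#' @return Readers return an [hg_kernel()].
#' @export
write_kernel_tsv <- function(kernel, path) {
  d <- data.frame(id = kernel$ids, kernel$K, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(kind = kernel$kind, ids = kernel$ids,
                            meta = kernel$meta),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @export
read_kernel_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  K <- as.matrix(d[, -1, drop = FALSE])
  rownames(K) <- d$id
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  hg_kernel(K, kind = side$kind, ids = d$id, meta = as.list(side$meta))
}

#' @rdname write_kernel_tsv
#' @export
write_kernel_bin <- function(kernel, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(kernel$K)), con, size = 8)
  jsonlite::write_json(list(kind = kernel$kind, n = nrow(kernel$K),
                            ids = kernel$ids, meta = kernel$meta),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @export
read_kernel_bin <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- side$n
  v <- readBin(path, "double", n = n * n, size = 8)
  K <- matrix(v, n, n, byrow = TRUE)
  hg_kernel(K, kind = side$kind, ids = side$ids, meta = as.list(side$meta))
}

#' Abundance-table I/O
#'
#' TSV layout: samples in rows (first column `id`), taxa in columns
#' (header row of taxon names). `read_abundance` also accepts a BIOM file
#' when the `biomformat` package is installed.
#'
#' @param ab samples x taxa matrix.
#' @param path file path.
#' @param format `"tsv"` or `"biom"` (read only).
#' @return `read_abundance` returns a numeric matrix.
#' @export
write_abundance_tsv <- function(ab, path) {
  d <- data.frame(id = rownames(ab), ab, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      hg_stop("reading BIOM needs the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))    # taxa x samples in BIOM
    return(t(m))
  }
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$id
  m
}

#' Phenotype-table I/O
#'
#' @param pheno data.frame (first column `id`).
#' @param path file path.
#' @return `read_phenotypes_tsv` returns a data.frame.
#' @export
write_phenotypes_tsv <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
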