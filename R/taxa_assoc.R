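# Taxon-phenotype association: two-part (hurdle) model, extreme-group
# ANOVA and Wilcoxon tests, Pearson screening, and the consensus rule.

#' Detection-rate filter for association testing
#'
#' Retains taxa present in strictly more than `min_detection` of the
#' samples (low-detection taxa carry too little information for
#' association).
#'
#' @param ab samples x taxa relative-abundance matrix.
#' @param min_detection detection threshold (default 0.30).
#' @return The filtered abundance matrix.
#' @export
filter_taxa_for_association <- function(ab, min_detection = 0.30) {
  ab <- as.matrix(ab)
  ab[, detection_rates(ab) > min_detection, drop = FALSE]
}

#' Two-part (hurdle) taxon-phenotype association
#'
#' Binary part: regress the phenotype on the presence indicator over all
#' samples. Quantitative part: regress the phenotype on the standardised
#' log(abundance + 1) over the samples where the taxon is present. Each
#' part gives a two-sided p-value; the verdict follows the 0.05 rules
#' (presence-associated, abundance-associated, both, neither). A taxon
#' present in every sample has no binary part (p recorded missing, verdict
#' from the quantitative part alone); fewer than 3 present samples drop the
#' quantitative part.
#'
#' @param y phenotype vector.
#' @param taxon abundance vector for one taxon.
#' @param alpha significance level for the verdict (default 0.05).
#' @return One-row data.frame: `p_binary`, `beta_binary`, `p_quant`,
#'   `beta_quant`, `verdict`.
#' @export
two_part_association <- function(y, taxon, alpha = 0.05) {
  ok <- is.finite(y) & is.finite(taxon)
  y <- y[ok]; taxon <- taxon[ok]
  b <- as.numeric(taxon > 0)
  p_b <- beta_b <- NA_real_
  if (var(b) > 0) {
    fit <- summary(lm(y ~ b))$coefficients
    beta_b <- fit["b", 1]; p_b <- fit["b", 4]
  }
  p_q <- beta_q <- NA_real_
  pres <- taxon > 0
  if (sum(pres) >= 3) {
    q <- log(taxon[pres] + 1)
    if (sd(q) > 0) {
      q <- as.numeric(scale(q))
      yq <- y[pres]
      if (sd(yq) > 0) {
        fit <- summary(lm(yq ~ q))$coefficients
        if (nrow(fit) == 2) { beta_q <- fit["q", 1]; p_q <- fit["q", 4] }
      }
    }
  }
  sig_b <- !is.na(p_b) && p_b < alpha
  sig_q <- !is.na(p_q) && p_q < alpha
  verdict <- if (sig_b && sig_q) "both"
  else if (sig_b) "presence-associated"
  else if (sig_q) "abundance-associated"
  else "neither"
  data.frame(p_binary = p_b, beta_binary = beta_b,
             p_quant = p_q, beta_quant = beta_q,
             verdict = verdict, stringsAsFactors = FALSE)
}

# Stable extreme-group indices: bottom/top floor(n * frac) by `by`,
# ties at the cutoff broken by original (sample ID) order.
extreme_groups <- function(by, frac) {
  n <- length(by)
  m <- floor(n * frac)
  if (m < 2) hg_stop("extreme groups need >= 2 samples each")
  ord <- order(by)                       # stable in R: ties keep input order
  list(low = ord[seq_len(m)], high = ord[seq(n - m + 1, n)], size = m)
}

#' Extreme-group ANOVA on the phenotype
#'
#' One-way ANOVA of the phenotype between the samples with the highest and
#' lowest abundances of a taxon (group size `floor(n * frac)`; 36 at
#' n = 361 and frac = 0.10).
#'
#' @param y phenotype vector.
#' @param taxon abundance vector.
#' @param frac extreme fraction per tail (default 0.10).
#' @return List with `p`, `mean_low`, `mean_high`, `group_size`, `flag`.
#' @export
extreme_group_anova <- function(y, taxon, frac = 0.10) {
  gr <- extreme_groups(taxon, frac)
  y1 <- y[gr$low]; y2 <- y[gr$high]
  flag <- NA_character_
  if (sd(c(y1, y2)) == 0) {
    p <- 1; flag <- "constant phenotype"
  } else {
    grp <- factor(rep(c("low", "high"), c(length(y1), length(y2))))
    p <- anova(lm(c(y1, y2) ~ grp))$`Pr(>F)`[1]
  }
  list(p = p, mean_low = mean(y1), mean_high = mean(y2),
       group_size = gr$size, flag = flag)
}

#' Extreme-group Wilcoxon rank-sum test on abundance
#'
#' Compares a taxon's relative abundance between the samples with the
#' highest and lowest phenotypic rankings (group size `floor(n * frac)`).
#' Exact null distribution when the combined group size is at most 20 and
#' there are no ties; tie-corrected normal approximation otherwise.
#'
#' @param taxon abundance vector.
#' @param y phenotype vector (grouping variable).
#' @param frac extreme fraction per tail.
#' @return List with `p`, `group_size`, `flag`.
#' @export
extreme_group_wilcoxon <- function(taxon, y, frac = 0.10) {
  gr <- extreme_groups(y, frac)
  a1 <- taxon[gr$low]; a2 <- taxon[gr$high]
  if (length(unique(c(a1, a2))) == 1)
    return(list(p = 1, group_size = gr$size, flag = "all tied"))
  exact <- (length(a1) + length(a2)) <= 20 && !anyDuplicated(c(a1, a2))
  wt <- suppressWarnings(wilcox.test(a1, a2, exact = exact,
                                     correct = !exact))
  list(p = wt$p.value, group_size = gr$size, flag = NA_character_)
}

#' Pearson correlation screen across taxa
#'
#' Per-taxon Pearson correlation with the phenotype; a taxon passes iff
#' `|r| > r_min` and p < alpha (the effect-size gate keeps significant but
#' negligible correlations out).
#'
#' @param y phenotype vector.
#' @param taxa samples x taxa abundance matrix.
#' @param r_min effect-size gate (default 0.1).
#' @param alpha significance level.
#' @return data.frame: `taxon`, `r`, `p`, `pass`, `flag`.
#' @export
pearson_screen <- function(y, taxa, r_min = 0.1, alpha = 0.05) {
  taxa <- as.matrix(taxa)
  nm <- colnames(taxa) %||% paste0("taxon", seq_len(ncol(taxa)))
  rows <- lapply(seq_len(ncol(taxa)), function(j) {
    x <- taxa[, j]
    cc <- is.finite(x) & is.finite(y)
    if (sum(cc) < 3 || sd(x[cc]) == 0 || sd(y[cc]) == 0)
      return(data.frame(taxon = nm[j], r = NA_real_, p = NA_real_,
                        pass = FALSE, flag = "degenerate",
                        stringsAsFactors = FALSE))
    ct <- cor.test(x[cc], y[cc])
    data.frame(taxon = nm[j], r = unname(ct$estimate), p = ct$p.value,
               pass = abs(ct$estimate) > r_min && ct$p.value < alpha,
               flag = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consensus across test families
#'
#' Within each family (two-part, extreme-group ANOVA, extreme-group
#' Wilcoxon) p-values are Benjamini-Hochberg adjusted across taxa per
#' trait; a (taxon, trait) pair is flagged iff all three adjusted p-values
#' are below `alpha`. The Pearson screen is carried along for reporting.
#' Pairs missing any of the three tests are recorded incomplete and never
#' flagged. Per-family significant counts and all overlaps are reported.
#'
#' @param two_part,anova,wilcoxon data.frames with columns `taxon`,
#'   `trait`, `p` (for two-part, `p` is the minimum of the available part
#'   p-values).
#' @param pearson optional data.frame with `taxon`, `trait`, `r`, `p`,
#'   `pass`.
#' @param alpha significance level on adjusted p-values.
#' @param method p-adjustment method (default `"BH"`).
#' @return List with `table` (per-pair adjusted p-values and flag) and
#'   `counts` (per-family and overlap counts).
#' @export
consensus <- function(two_part, anova, wilcoxon, pearson = NULL,
                      alpha = 0.05, method = "BH") {
  adj <- function(d) {
    d$p_adj <- NA_real_
    for (tr in unique(d$trait)) {
      i <- d$trait == tr
      d$p_adj[i] <- p.adjust(d$p[i], method = method)
    }
    d
  }
  tp <- adj(two_part); an <- adj(anova); wx <- adj(wilcoxon)
  key <- function(d) paste(d$taxon, d$trait, sep = "\r")
  pairs <- unique(rbind(tp[c("taxon", "trait")], an[c("taxon", "trait")],
                        wx[c("taxon", "trait")]))
  tab <- data.frame(taxon = pairs$taxon, trait = pairs$trait,
                    stringsAsFactors = FALSE)
  tab$p_two_part <- tp$p_adj[match(key(tab), key(tp))]
  tab$p_anova <- an$p_adj[match(key(tab), key(an))]
  tab$p_wilcoxon <- wx$p_adj[match(key(tab), key(wx))]
  if (!is.null(pearson)) {
    tab$pearson_r <- pearson$r[match(key(tab), key(pearson))]
    tab$pearson_pass <- pearson$pass[match(key(tab), key(pearson))]
  }
  tab$incomplete <- is.na(tab$p_two_part) | is.na(tab$p_anova) |
    is.na(tab$p_wilcoxon)
  tab$flag <- !tab$incomplete & tab$p_two_part < alpha &
    tab$p_anova < alpha & tab$p_wilcoxon < alpha
  s_tp <- !is.na(tab$p_two_part) & tab$p_two_part < alpha
  s_an <- !is.na(tab$p_anova) & tab$p_anova < alpha
  s_wx <- !is.na(tab$p_wilcoxon) & tab$p_wilcoxon < alpha
  counts <- list(two_part = sum(s_tp), anova = sum(s_an),
                 wilcoxon = sum(s_wx),
                 two_part_anova = sum(s_tp & s_an),
                 two_part_wilcoxon = sum(s_tp & s_wx),
                 anova_wilcoxon = sum(s_an & s_wx),
                 all_three = sum(s_tp & s_an & s_wx))
  list(table = tab, counts = counts)
}

#' Full taxon-association pipeline for several traits
#'
#' Applies the 30% detection filter, then for every retained taxon and
#' every trait runs the two-part model, extreme-group ANOVA, extreme-group
#' Wilcoxon and Pearson screen, and combines them with [consensus()].
#'
#' @param pheno data.frame of phenotypes (rows aligned with `ab`).
#' @param traits character vector of phenotype columns to analyse.
#' @param ab samples x taxa relative-abundance matrix.
#' @param frac extreme-group fraction (default 0.10).
#' @param min_detection detection filter (default 0.30).
#' @param alpha significance level.
#' @return List with per-test data.frames (`two_part`, `anova`,
#'   `wilcoxon`, `pearson`) and the `consensus` report.
#' @export
associate_taxa <- function(pheno, traits, ab, frac = 0.10,
                           min_detection = 0.30, alpha = 0.05) {
  ab <- filter_taxa_for_association(ab, min_detection)
  taxa <- colnames(ab)
  tp <- an <- wx <- pe <- NULL
  for (tr in traits) {
    y <- pheno[[tr]]
    if (is.null(y)) hg_stop("trait column not found: ", tr)
    for (tx in taxa) {
      v <- ab[, tx]
      r1 <- two_part_association(y, v, alpha)
      tp <- rbind(tp, data.frame(taxon = tx, trait = tr,
                                 p = suppressWarnings(
                                   min(c(r1$p_binary, r1$p_quant),
                                       na.rm = TRUE)),
                                 verdict = r1$verdict,
                                 stringsAsFactors = FALSE))
      r2 <- extreme_group_anova(y, v, frac)
      an <- rbind(an, data.frame(taxon = tx, trait = tr, p = r2$p,
                                 stringsAsFactors = FALSE))
      r3 <- extreme_group_wilcoxon(v, y, frac)
      wx <- rbind(wx, data.frame(taxon = tx, trait = tr, p = r3$p,
                                 stringsAsFactors = FALSE))
    }
    ps <- pearson_screen(y, ab, alpha = alpha)
    ps$trait <- tr
    pe <- rbind(pe, ps)
  }
  tp$p[!is.finite(tp$p)] <- NA_real_
  list(two_part = tp, anova = an, wilcoxon = wx, pearson = pe,
       consensus = consensus(tp, an, wx, pe, alpha = alpha))
}
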