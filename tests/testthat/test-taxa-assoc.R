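# Two-part model, extreme-group tests, Pearson screen, consensus.

test_that("the 30% detection filter is strict and countable", {
  ab <- fixture_abundance(n = 100, detects = c(0.29, 0.31, 0.50, 1.0))
  kept <- filter_taxa_for_association(ab)
  expect_setequal(colnames(kept), c("tax2", "tax3", "tax4"))

  set.seed(51)
  rates <- round(runif(100, 0.05, 1), 2)
  ab2 <- fixture_abundance(n = 100, detects = rates, seed = 52)
  kept2 <- filter_taxa_for_association(ab2)
  # counting oracle on the actually realised detection rates
  realised <- apply(ab2, 2, function(v) sum(v > 0) / length(v))
  expect_equal(ncol(kept2), sum(realised > 0.30))
})

test_that("two-part model separates presence and abundance signals", {
  set.seed(53)
  ab <- fixture_abundance(n = 400, detects = rep(0.6, 3), seed = 53)
  v <- ab[, 1]

  # phenotype equal to the presence indicator: binary part explodes
  res <- two_part_association(as.numeric(v > 0) + rnorm(400, 0, 1e-3), v)
  expect_lt(res$p_binary, 1e-10)
  expect_equal(res$verdict, "presence-associated")

  # abundance-driven phenotype: quantitative verdict dominates
  verdicts <- character(20)
  for (r in 1:20) {
    set.seed(5300 + r)
    abx <- fixture_abundance(n = 400, detects = 0.6, seed = 5300 + r)
    vx <- abx[, 1]
    q_full <- rep(0, 400)
    pres <- vx > 0
    q_full[pres] <- scale(log(vx[pres] + 1))
    y <- 0.5 * q_full + rnorm(400)
    verdicts[r] <- two_part_association(y, vx)$verdict
  }
  expect_gte(sum(verdicts %in% c("abundance-associated", "both")), 18)

  # taxon present everywhere: binary part undefined
  all_pres <- runif(50, 0.1, 1)
  res2 <- two_part_association(2 * log(all_pres + 1) + rnorm(50, 0, 0.1),
                               all_pres)
  expect_true(is.na(res2$p_binary))
  expect_equal(res2$verdict, "abundance-associated")

  # fewer than 3 present samples: quantitative part missing
  sparse <- c(0.5, 0.4, rep(0, 48))
  res3 <- two_part_association(rnorm(50), sparse)
  expect_true(is.na(res3$p_quant))
})

test_that("two-part null type-I error is near nominal", {
  set.seed(54)
  n <- 200
  pb <- pq <- numeric(500)
  for (r in 1:500) {
    ab <- fixture_abundance(n = n, detects = 0.5, seed = 5400 + r)
    y <- rnorm(n)
    res <- two_part_association(y, ab[, 1])
    pb[r] <- res$p_binary; pq[r] <- res$p_quant
  }
  for (p in list(pb, pq)) {
    rate <- mean(p < 0.05, na.rm = TRUE)
    ci <- qbinom(c(0.005, 0.995), 500, 0.05) / 500
    expect_gte(rate, ci[1] - 1e-9)
    expect_lte(rate, ci[2] + 1e-9)
  }
})

test_that("extreme-group ANOVA uses floor(n frac) and equals t^2", {
  set.seed(55)
  taxon <- runif(361); y <- rnorm(361)
  res <- extreme_group_anova(y, taxon, frac = 0.10)
  expect_equal(res$group_size, 36)

  resc <- extreme_group_anova(rep(1, 100), runif(100))
  expect_equal(resc$p, 1)
  expect_equal(resc$flag, "constant phenotype")

  # F = t^2 on a toy instance
  y2 <- rnorm(40); tax2 <- runif(40)
  gr_lo <- order(tax2)[1:4]; gr_hi <- order(tax2)[37:40]
  tt <- t.test(y2[gr_lo], y2[gr_hi], var.equal = TRUE)
  res2 <- extreme_group_anova(y2, tax2, frac = 0.10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
})

test_that("extreme-group Wilcoxon matches exhaustive enumeration", {
  # groups (1,2,3) vs (4,5,6): exact two-sided p = 0.1
  y <- 1:30                       # phenotype ranks pick first/last 3
  taxon <- c(1, 2, 3, rep(3.5, 24), 4, 5, 6)
  res <- extreme_group_wilcoxon(taxon, y, frac = 0.10)
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_equal(res$p, oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)

  tied <- rep(0.3, 30)
  expect_equal(extreme_group_wilcoxon(tied, y, frac = 0.10)$p, 1)

  # uniform under the null (normal-approximation branch)
  set.seed(56)
  pv <- replicate(300, {
    extreme_group_wilcoxon(runif(200), rnorm(200), frac = 0.10)$p
  })
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pearson screen applies the |r| > 0.1 effect-size gate", {
  set.seed(57)
  n <- 1000
  x <- rnorm(n)
  z <- residuals(lm(rnorm(n) ~ x))
  mk_exact_r <- function(r) {
    v <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(z)[, 1]
    as.numeric(v)
  }
  y_small <- mk_exact_r(0.09)      # significant but below the gate
  taxa <- cbind(t1 = x - min(x) + 0.1, t2 = rep(0.5, n))
  out <- pearson_screen(y_small, taxa)
  expect_equal(out$r[1], 0.09, tolerance = 1e-10)
  expect_lt(out$p[1], 0.05)
  expect_false(out$pass[1])
  expect_identical(out$flag[2], "degenerate")

  # exact linear relation passes
  lin <- pearson_screen(2 * taxa[1:10, 1] + 1,
                        taxa[1:10, , drop = FALSE])
  expect_true(lin$pass[1])
  expect_equal(lin$r[1], 1, tolerance = 1e-12)

  # closed-form oracle for r and p
  set.seed(58)
  xo <- runif(12); yo <- 0.4 * xo + rnorm(12, 0, 0.3)
  sc <- pearson_screen(yo, cbind(tax = xo))
  r_hand <- sum((xo - mean(xo)) * (yo - mean(yo))) /
    sqrt(sum((xo - mean(xo))^2) * sum((yo - mean(yo))^2))
  p_hand <- 2 * pt(-abs(r_hand * sqrt(10 / (1 - r_hand^2))), 10)
  expect_equal(sc$r, r_hand, tolerance = 1e-10)
  expect_equal(sc$p, p_hand, tolerance = 1e-10)
})

test_that("consensus flags require all three adjusted tests", {
  taxa <- paste0("t", 1:10)
  mk <- function(pvec) data.frame(taxon = taxa, trait = "y", p = pvec)
  p_null <- rep(0.8, 10); p_null[1] <- 0.001
  rep1 <- consensus(mk(p_null), mk(p_null), mk(p_null))
  expect_true(rep1$table$flag[rep1$table$taxon == "t1"])
  expect_equal(sum(rep1$table$flag), 1)

  # set-operations oracle for the overlap counts
  set.seed(59)
  ps <- replicate(3, ifelse(runif(10) < 0.4, 1e-4, 0.9))
  rep2 <- consensus(mk(ps[, 1]), mk(ps[, 2]), mk(ps[, 3]))
  sig <- lapply(1:3, function(j)
    taxa[p.adjust(ps[, j], "BH") < 0.05])
  expect_equal(rep2$counts$two_part, length(sig[[1]]))
  expect_equal(rep2$counts$anova_wilcoxon,
               length(intersect(sig[[2]], sig[[3]])))
  expect_equal(rep2$counts$all_three,
               length(Reduce(intersect, sig)))

  # a pair missing one family is incomplete and never flagged
  rep3 <- consensus(mk(p_null)[-1, ], mk(p_null), mk(p_null))
  row1 <- rep3$table[rep3$table$taxon == "t1", ]
  expect_true(row1$incomplete)
  expect_false(row1$flag)
})

test_that("the full association pipeline recovers planted taxa", {
  set.seed(60)
  n <- 400
  ab <- fixture_abundance(n = n, detects = runif(60, 0.35, 0.98),
                          seed = 61)
  planted <- 1:5
  signal <- rowSums(scale(log(ab[, planted] + 1)))
  y <- 0.5 * signal + rnorm(n)
  pheno <- data.frame(id = seq_len(n), y = y)
  res <- associate_taxa(pheno, "y", ab)

  flagged <- res$consensus$table$taxon[res$consensus$table$flag]
  det <- detection_rates(ab)
  expect_true(all(det[flagged] > 0.30))          # flag => passed filter
  expect_true(all(flagged %in% colnames(ab)))
  hits <- sum(colnames(ab)[planted] %in% flagged)
  expect_gte(hits, 3)                            # enrichment for truth
  false_flags <- sum(!flagged %in% colnames(ab)[planted])
  expect_lte(false_flags, max(1, length(flagged) * 0.1))

  # under the global null almost nothing is flagged
  n_flag <- 0L; n_pairs <- 0L
  for (r in 1:10) {
    abn <- fixture_abundance(n = 150, detects = runif(40, 0.35, 0.95),
                             seed = 6200 + r)
    set.seed(6300 + r)
    ph <- data.frame(id = 1:150, y = rnorm(150))
    cn <- associate_taxa(ph, "y", abn)$consensus$table
    n_flag <- n_flag + sum(cn$flag)
    n_pairs <- n_pairs + nrow(cn)
  }
  expect_lt(n_flag / n_pairs, 0.01)
})
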