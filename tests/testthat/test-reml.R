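# REML estimation against the grid-search oracle, LRT calibration,
# trait classification, and the heritability screen.

test_that("single-kernel REML matches the variance-ratio grid search", {
  set.seed(31)
  for (case in 1:4) {
    n <- c(25, 30, 40, 36)[case]
    h_true <- c(0.0, 0.3, 0.6, 0.9)[case]
    X <- cbind(1, rnorm(n))
    W <- matrix(rnorm(n * 60), n)
    K <- tcrossprod(W) / 60
    u <- drop(t(chol(K + 1e-8 * diag(n))) %*% rnorm(n)) * sqrt(h_true)
    y <- drop(X %*% c(1, 0.5)) + u + rnorm(n, 0, sqrt(1 - h_true))
    fit <- fit_reml(y, X, list(K))
    oracle <- oracle_reml_grid(y, X, K)
    expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)
    expect_gte(fit$loglik, oracle$loglik - 1e-6)  # never below the grid
    # forced AI path lands on the same optimum
    fit_ai <- fit_reml(y, X, list(K), use_eigen = FALSE)
    expect_lt(abs(fit_ai$loglik - oracle$loglik), 1e-4)
    expect_lt(abs(fit_ai$ratios[1] - fit$ratios[1]), 5e-3)
  }
})

test_that("pure-noise traits yield a near-zero kernel ratio", {
  # the microbial kernel has a well-identified ratio (wide off-diagonal
  # spread), so sigma_m^2 -> 0 is sharp at this n; a GRM built from
  # unrelated HWE samples would only bound the ratio loosely
  cfg <- sim_config(n_individuals = 400, n_snps = 50, n_taxa = 205,
                    seed = 32)
  g <- simulate_genotypes(cfg)
  M <- compute_mrm(simulate_microbiome(cfg, g)$abundance)
  set.seed(33)
  ratios <- replicate(5, fit_reml(rnorm(400), NULL, list(M))$ratios[1])
  expect_lt(mean(ratios), 0.05)
})

test_that("ratios are normalised, scale-invariant, and well-formed", {
  cfg <- sim_config(n_individuals = 150, n_snps = 800, n_taxa = 60,
                    variance_fractions = c(0.4, 0.2, 0),
                    fixed_effects = list(sex = 0, pen = 0, onbw = 0),
                    seed = 34)
  g <- simulate_genotypes(cfg)
  mb <- simulate_microbiome(cfg, g)
  G <- compute_grm(g); M <- compute_mrm(mb$abundance)
  ph <- simulate_phenotypes(cfg, G, M)
  y <- ph$pheno$y
  f1 <- fit_reml(y, NULL, list(G, M))
  expect_equal(sum(f1$ratios), 1, tolerance = 1e-8)
  expect_true(all(f1$ratios >= 0 & f1$ratios <= 1))
  expect_gt(sum(f1$variances), 0)
  f2 <- fit_reml(y * 37.5, NULL, list(G, M))
  expect_equal(unname(f1$ratios), unname(f2$ratios), tolerance = 1e-8)
})

test_that("fit_reml validates its inputs", {
  y <- rnorm(20)
  expect_error(fit_reml(c(y, NA), NULL, list(diag(21))), "complete")
  expect_error(fit_reml(y, cbind(1, rep(2, 20)), list(diag(20))),
               "singular")
  expect_error(fit_reml(y, NULL, list(diag(5))), "dimension")
  expect_error(fit_reml(rnorm(3), NULL, list(diag(3), diag(3), diag(3))),
               "need n >")
})

test_that("component p-values follow the 50:50 boundary mixture", {
  mk <- function(ll) structure(list(loglik = ll), class = "hg_varcomp")
  expect_equal(component_pvalue(mk(10), mk(10)), 0.5)
  expect_equal(component_pvalue(mk(10 + 2.706 / 2), mk(10)), 0.05,
               tolerance = 1e-3)
  expect_warning(p <- component_pvalue(mk(10), mk(10.1)), "negative")
  expect_equal(p, 0.5)
})

test_that("the boundary LRT is calibrated under the null", {
  reps <- 300
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_individuals = 200, n_snps = 500, n_taxa = 2,
                      seed = 4000 + r)
    G <- compute_grm(simulate_genotypes(cfg))
    set.seed(8000 + r)
    y <- rnorm(200)
    full <- fit_reml(y, NULL, list(G))
    null <- fit_reml(y, NULL, list())
    rej[r] <- component_pvalue(full, null) < 0.05
  }
  ci <- qbinom(c(0.005, 0.995), reps, 0.05) / reps
  expect_gte(mean(rej), ci[1] - 1e-9)
  expect_lte(mean(rej), ci[2] + 1e-9)
})

test_that("heritability and microbiability wrappers recover planted truth", {
  reps <- 10
  h_est <- m_est <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_individuals = 300, n_snps = 3000, n_taxa = 300,
                      variance_fractions = c(genetic = 0.46,
                                             microbiome = 0, interaction = 0),
                      fixed_effects = list(sex = 0, pen = 0, onbw = 0),
                      seed = 500 + r)
    g <- simulate_genotypes(cfg)
    G <- compute_grm(g)
    ph <- simulate_phenotypes(cfg, G)
    h_est[r] <- estimate_heritability(ph$pheno$y, NULL, G)$h2

    cfgm <- cfg
    cfgm$variance_fractions <- c(genetic = 0, microbiome = 0.2,
                                 interaction = 0)
    mb <- simulate_microbiome(cfgm, g)
    M <- compute_mrm(mb$abundance)
    phm <- simulate_phenotypes(cfgm, NULL, M)
    m_est[r] <- estimate_microbiability(phm$pheno$y, NULL, M)$m2
  }
  # scaled-down mirror of the full-size acceptance recovery; the per-rep
  # SD of h2-hat on unrelated HWE panels is ~0.26, hence the wide band
  expect_lt(abs(mean(h_est) - 0.46), 0.25)
  expect_lt(abs(mean(m_est) - 0.20), 0.08)

  # permuting y against the kernel destroys the signal
  cfg <- sim_config(n_individuals = 300, n_snps = 500, n_taxa = 205,
                    variance_fractions = c(0, 0.5, 0),
                    fixed_effects = list(sex = 0, pen = 0, onbw = 0),
                    seed = 600)
  g <- simulate_genotypes(cfg)
  M <- compute_mrm(simulate_microbiome(cfg, g)$abundance)
  ph <- simulate_phenotypes(cfg, NULL, M)
  set.seed(601)
  est <- estimate_microbiability(sample(ph$pheno$y), NULL, M)
  expect_lt(est$m2, 0.1)
})

test_that("detection-rate classification follows the 60/30 rules", {
  expect_equal(as.character(classify_microbial_trait(0.70)), "quantitative")
  expect_equal(as.character(classify_microbial_trait(0.45)), "binary")
  expect_equal(as.character(classify_microbial_trait(0.60)), "binary")
  expect_equal(as.character(classify_microbial_trait(0.30)), "binary")
  expect_equal(as.character(classify_microbial_trait(0.29)), "excluded")
  expect_error(classify_microbial_trait(1.2), "detection")
})

test_that("the genus heritability screen finds planted heritable taxa", {
  cfg <- sim_config(n_individuals = 250, n_snps = 1500, n_taxa = 60,
                    detection_profile = c(rep(0.9, 10),
                                          seq(0.2, 0.95, length.out = 50)),
                    seed = 35)
  g <- simulate_genotypes(cfg)
  spec <- lapply(1:10, function(j)
    list(taxon = j, snps = ((j - 1) * 20 + 1):((j - 1) * 20 + 10),
         effects = rnorm(10), h2 = 0.6))
  set.seed(36)
  mb <- simulate_microbiome(cfg, g, spec)
  G <- compute_grm(g)
  scr <- genus_heritability_screen(mb$abundance, NULL, G)

  expect_false(any(scr$mode == "excluded"))
  det <- detection_rates(mb$abundance)
  expect_setequal(scr$taxon,
                  colnames(mb$abundance)[det >= 0.30])

  planted <- scr$taxon %in% colnames(mb$abundance)[1:10]
  expect_gt(mean(scr$significant[planted]), mean(scr$significant[!planted]))
  expect_lte(mean(scr$significant[!planted]), 0.15)  # near-nominal nulls
})
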