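# deterministic synthetic cells table with known group structure
make_table <- function(n_per = 8, means = NULL, sd = 1, seed = 1,
                       species = c("Apis", "Bombus"),
                       regions = c("main_retina", "marginal_DRA", "DRA")) {
  set.seed(seed)
  if (is.null(means)) {
    means <- expand.grid(species = species, eye_region = regions,
                         stringsAsFactors = FALSE)
    means$mu <- 5
  }
  do.call(rbind, lapply(seq_len(nrow(means)), function(i) {
    data.frame(species = means$species[i], eye_region = means$eye_region[i],
               ps = rnorm(n_per, means$mu[i], sd),
               fwhm_circ = rnorm(n_per, means$mu[i], sd))
  }))
}

test_that("two-way ANOVA agrees with explicit normal-equation sums of squares", {
  tab <- make_table(n_per = 6, seed = 4,
                    regions = c("main_retina", "DRA"))
  tab$ps <- tab$ps + ifelse(tab$eye_region == "DRA", 3, 0) +
    ifelse(tab$species == "Bombus", -1, 0)
  an <- two_way_anova(tab, "ps")

  # brute-force oracle: residual sums of squares of the three candidate
  # models via explicit design matrices and normal equations
  rss <- function(X, y) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  y <- tab$ps
  a <- as.numeric(tab$species == "Bombus")
  b <- as.numeric(tab$eye_region == "DRA")
  rss_full <- rss(cbind(1, a, b), y)
  ss_species <- rss(cbind(1, b), y) - rss_full
  ss_region <- rss(cbind(1, a), y) - rss_full
  df_res <- nrow(tab) - 3
  expect_equal(an$table$sum_sq, c(ss_species, ss_region), tolerance = 1e-10)
  expect_equal(an$table$f,
               c(ss_species, ss_region) / (rss_full / df_res),
               tolerance = 1e-10)
  expect_equal(an$df_residual, df_res)
})

test_that("ANOVA null and extreme-effect behaviour", {
  null_tab <- make_table(n_per = 10, seed = 2)
  an <- two_way_anova(null_tab, "fwhm_circ")
  expect_true(all(an$table$p > 0.01))    # no effect built in

  shift <- make_table(n_per = 10, seed = 3)
  shift$ps <- shift$ps + ifelse(shift$eye_region == "DRA", 10, 0)
  an2 <- two_way_anova(shift, "ps")
  expect_lt(an2$table$p[an2$table$term == "eye_region"], 1e-6)

  one_level <- make_table()
  one_level$species <- "Apis"
  expect_error(two_way_anova(one_level, "ps"), "2 levels")
})

test_that("ANOVA decomposition is exact on balanced designs", {
  tab <- make_table(n_per = 7, seed = 6)
  tab$ps <- tab$ps + ifelse(tab$eye_region == "DRA", 2, 0)
  an <- two_way_anova(tab, "ps")
  rss_full <- sum(an$residuals^2)
  ss_total <- sum((tab$ps - mean(tab$ps))^2)
  expect_equal(sum(an$table$sum_sq) + rss_full, ss_total,
               tolerance = 1e-9 * ss_total)
})

test_that("shapiro_wilk calibration under null and skewed alternative", {
  p_null <- vapply(1:100, function(s) {
    set.seed(s); shapiro_wilk(rnorm(50))$p
  }, numeric(1))
  expect_gte(mean(p_null > 0.01), 0.95)

  p_skew <- vapply(1:100, function(s) {
    set.seed(s); shapiro_wilk(exp(rnorm(50)))$p
  }, numeric(1))
  expect_gte(mean(p_skew < 0.01), 0.95)

  expect_error(shapiro_wilk(rep(1, 10)), "zero variance")
  expect_error(shapiro_wilk(rnorm(2)), "3 <= n")
})

test_that("tukey_hsd mean differences equal direct group-mean subtraction", {
  tab <- make_table(n_per = 10, seed = 9, species = "Apis")
  tab$fwhm_circ <- tab$fwhm_circ +
    c(main_retina = 0, marginal_DRA = 2.5,
      DRA = 4.1)[tab$eye_region]
  tk <- tukey_hsd(tab, "fwhm_circ")
  gm <- tapply(tab$fwhm_circ, tab$eye_region, mean)
  for (i in seq_len(nrow(tk$comparisons))) {
    want <- gm[tk$comparisons$group1[i]] - gm[tk$comparisons$group2[i]]
    expect_equal(tk$comparisons$mean_diff[i], unname(want),
                 tolerance = 1e-12)
  }
})

test_that("tukey_hsd letters reflect the significance structure", {
  same <- make_table(n_per = 10, seed = 16, species = "Apis")
  tk0 <- tukey_hsd(same, "ps")
  expect_true(all(tk0$comparisons$p_adj > 0.5))
  expect_length(unique(tk0$letters), 1L)   # one shared letter

  far <- make_table(n_per = 10, seed = 11, species = "Apis")
  far$ps <- far$ps + ifelse(far$eye_region == "DRA", 10, 0)
  tk1 <- tukey_hsd(far, "ps")
  expect_false(tk1$letters[["DRA"]] %in%
                 tk1$letters[c("main_retina", "marginal_DRA")])

  # a group with < 2 observations is flagged and excluded
  small <- rbind(far, data.frame(species = "Apis", eye_region = "tiny",
                                 ps = 1, fwhm_circ = 1))
  tk2 <- tukey_hsd(small, "ps")
  expect_equal(tk2$flagged_groups, "tiny")
})

test_that("Tukey adjusted p is conservative relative to pairwise t", {
  tab <- make_table(n_per = 8, seed = 12, species = "Apis")
  tab$ps <- tab$ps + c(main_retina = 0, marginal_DRA = 1,
                       DRA = 2)[tab$eye_region]
  tk <- tukey_hsd(tab, "ps")
  fit <- stats::aov(ps ~ eye_region, data = transform(
    tab, eye_region = factor(eye_region)))
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  gm <- tapply(tab$ps, tab$eye_region, mean)
  nn <- table(tab$eye_region)
  for (i in seq_len(nrow(tk$comparisons))) {
    g1 <- tk$comparisons$group1[i]; g2 <- tk$comparisons$group2[i]
    tstat <- abs(gm[g1] - gm[g2]) /
      sqrt(mse * (1 / nn[g1] + 1 / nn[g2]))
    p_t <- 2 * stats::pt(-tstat, fit$df.residual)
    expect_gte(tk$comparisons$p_adj[i] + 1e-12, unname(p_t))
  }
})

test_that("FWHM ~ PS model recovers known coefficients", {
  set.seed(21)
  n <- 200
  tab <- data.frame(
    species = sample(c("Apis", "Bombus"), n, replace = TRUE),
    eye_region = sample(c("main_retina", "marginal_DRA", "DRA"), n,
                        replace = TRUE),
    ps = runif(n, 1, 12))
  beta <- c(intercept = 3, ps = 0, bombus = -0.6, marg = 2.2, dra = 3.8)
  mu <- beta["intercept"] + beta["ps"] * tab$ps +
    beta["bombus"] * (tab$species == "Bombus") +
    beta["marg"] * (tab$eye_region == "marginal_DRA") +
    beta["dra"] * (tab$eye_region == "DRA")
  tab$fwhm_circ <- mu + rnorm(n, 0, 0.5)
  fit <- fit_fwhm_ps_model(tab)
  cf <- fit$coefficients
  expect_equal(cf$term,
               c("(Intercept)", "ps", "speciesBombus",
                 "eye_regionmarginal_DRA", "eye_regionDRA"))
  for (i in seq_len(nrow(cf))) {
    expect_lt(abs(cf$estimate[i] -
                    beta[c("intercept", "ps", "bombus", "marg", "dra")][i]),
              2 * cf$se[i] + 1e-9)
  }
  # zero-noise interpolation: exact recovery against the normal equations
  tab0 <- tab; tab0$fwhm_circ <- mu
  # suppressed: summary.lm warns on an (intentionally) perfect fit
  cf0 <- suppressWarnings(fit_fwhm_ps_model(tab0))$coefficients
  expect_equal(cf0$estimate,
               unname(beta[c("intercept", "ps", "bombus", "marg", "dra")]),
               tolerance = 1e-10)
})

test_that("rank-deficient designs are reported with the collinear columns", {
  # species perfectly confounded with eye region
  tab <- data.frame(
    species = rep(c("Apis", "Bombus"), each = 10),
    eye_region = rep(c("main_retina", "DRA"), each = 10),
    ps = runif(20, 1, 10), fwhm_circ = runif(20, 2, 8))
  expect_error(fit_fwhm_ps_model(tab), "collinear")
})

test_that("statistics are bit-reproducible on a fixed table", {
  tab <- make_table(n_per = 6, seed = 31)
  r1 <- stats_report(tab)
  r2 <- stats_report(tab)
  expect_identical(r1, r2)
})
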