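# Cohort with one metabolite wired to the target lipid at a known
# standardized effect, via the structural model with no familial loadings.
wired_cohort <- function(seed, beta = 0.15, n_pairs = 2000) {
  sim <- simulate_twin_cohort(twin_cohort_spec(
    n_pairs = n_pairs, n_singletons = 0, familial_loading_x = 0,
    familial_loading_y = 0, causal_effect = beta,
    causal_direction = "x_to_y", missing_counts = NULL, seed = seed))
  mm <- simulate_metabolome(sim, metabolome_spec(
    n_metabolites = 1, lod_quantile = 0, frac_high_cv = 0,
    frac_low_occurrence = 0))
  z <- transform_metabolites(mm)
  dat <- transform_traits(sim$cohort)
  dat$TG <- as.numeric(scale(dat$TG))  # standardized log-lipid outcome
  dat$met <- z[match(dat$individual_id, rownames(z)), 1]
  dat
}

test_that("pair-clustered fit recovers a planted standardized effect", {
  betas <- vapply(1:20, function(s) {
    dat <- wired_cohort(600 + s)
    fit_association(dat, "met", "TG")$beta
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.15), 0.02)
  expect_lt(sd(betas), 0.03)
})

test_that("null metabolite gives near-zero beta and honest p-values", {
  ps <- vapply(1:40, function(s) {
    sim <- simulate_twin_cohort(twin_cohort_spec(
      n_pairs = 200, n_singletons = 0, familial_loading_x = 0.5,
      familial_loading_y = 0.5, causal_effect = 0, causal_direction = "none",
      missing_counts = NULL, seed = 700 + s))
    dat <- transform_traits(sim$cohort)
    set.seed(s)
    fit_association(dat, rnorm(nrow(dat)), "TG")$p_value
  }, numeric(1))
  # p uniform under the null: roughly 5% below 0.05, mean near 0.5
  expect_lt(mean(ps < 0.05), 0.20)
  expect_equal(mean(ps), 0.5, tolerance = 0.2)
})

test_that("with no within-pair residual correlation the fit collapses to OLS", {
  # anti-correlated within-pair residuals force the random-intercept variance
  # to its boundary (zero), so the clustered fit must equal OLS
  set.seed(801)
  n_pairs <- 150
  met <- rnorm(2 * n_pairs)
  u <- rnorm(n_pairs)
  dat <- data.frame(individual_id = as.character(1:(2 * n_pairs)),
                    pair_id = rep(sprintf("p%03d", 1:n_pairs), each = 2),
                    age = rep(rnorm(n_pairs, 50, 10), each = 2),
                    gender = rep(c("male", "female"), n_pairs),
                    TG = 0.2 * met + as.vector(rbind(u, -u)),
                    met = met)
  rec <- fit_association(dat, "met", "TG")
  ols <- lm(TG ~ met + age + gender, data = dat)
  expect_equal(rec$beta, unname(coef(ols)["met"]), tolerance = 1e-6)
  expect_equal(rec$se, unname(sqrt(diag(vcov(ols)))["met"]), tolerance = 1e-4)
  # the GEE backend estimates a negative working correlation here but the
  # same population coefficient
  rec_gee <- fit_association(dat, "met", "TG", engine = "gee")
  expect_lt(abs(rec_gee$beta - rec$beta), 0.05)
})

test_that("too few complete cases are refused", {
  dat <- wired_cohort(802, n_pairs = 40)
  dat$TG[-(1:5)] <- NA
  expect_error(fit_association(dat, "met", "TG"), "complete cases")
})

test_that("BH adjustment matches the hand-computed step-up oracle", {
  expect_equal(adjust_fdr(c(1, 1, 1, 1)), c(1, 1, 1, 1))
  # step-up by hand: p_(i) * m / i, cummin from the largest rank
  p <- c(0.01, 0.02, 0.03, 0.04)
  hand <- rev(cummin(rev(sort(p) * 4 / 1:4)))[order(order(p))]
  expect_equal(adjust_fdr(p), hand)
  expect_equal(adjust_fdr(p), rep(0.04, 4))
  expect_error(adjust_fdr(numeric(0)), "empty")
  # monotone non-decreasing in rank order; q >= p
  set.seed(10)
  p2 <- runif(50)
  q2 <- adjust_fdr(p2)
  expect_true(all(q2 >= p2))
  expect_true(all(diff(q2[order(p2)]) >= -1e-12))
})

test_that("family-wise BH over 248 null tests controls false calls near 5%", {
  set.seed(11)
  any_call <- vapply(1:1000, function(i) any(adjust_fdr(runif(248)) < 0.05),
                     logical(1))
  expect_gt(mean(any_call), 0.03)
  expect_lt(mean(any_call), 0.07)
})

test_that("record-level FDR is computed within each lipid family", {
  recs <- data.frame(metabolite = rep(c("m1", "m2"), 2),
                     lipid = rep(c("TG", "HDL_C"), each = 2),
                     p_value = c(0.01, 0.04, 0.5, 0.8),
                     converged = c(TRUE, TRUE, TRUE, FALSE))
  out <- adjust_fdr(recs)
  expect_equal(out$q_value[1:2], p.adjust(c(0.01, 0.04), "BH"))
  # non-converged record excluded from its family
  expect_true(is.na(out$q_value[4]))
  expect_equal(out$q_value[3], 0.5)
})

test_that("overweight stratification assigns BMI 24 to the overweight stratum", {
  dat <- wired_cohort(803, beta = 0.2, n_pairs = 300)
  dat$BMI[1] <- 24.0
  res <- stratified_interaction(dat, "met", "TG")
  n_ow <- res$n[res$model == "stratum_overweight"]
  expect_equal(n_ow, sum(dat$BMI >= 24, na.rm = TRUE))
  expect_equal(res$interaction_p[1], res$interaction_p[2])
  expect_true(res$interaction_p[1] >= 0 && res$interaction_p[1] <= 1)
})

test_that("interaction LRT is calibrated under equal effects and powered under unequal", {
  # type I: identical effect in both strata -> interaction P roughly uniform
  ps <- vapply(1:60, function(s) {
    dat <- wired_cohort(900 + s, beta = 0.2, n_pairs = 150)
    stratified_interaction(dat, "met", "TG")$interaction_p[1]
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.3)
  # power: effect 0 vs 0.3 by stratum
  ps2 <- vapply(1:15, function(s) {
    dat <- wired_cohort(950 + s, beta = 0, n_pairs = 1000)
    ow <- dat$BMI >= 24
    dat$TG <- ifelse(ow, dat$TG * sqrt(1 - 0.3^2) + 0.3 * dat$met, dat$TG)
    stratified_interaction(dat, "met", "TG")$interaction_p[1]
  }, numeric(1))
  expect_gt(mean(ps2 < 0.05), 0.8)
})

test_that("BMI adjustment leaves an unconfounded effect untouched", {
  dat <- wired_cohort(804, beta = 0.2, n_pairs = 1500)
  r0 <- fit_association(dat, "met", "TG")
  r1 <- fit_association(dat, "met", "TG", adjust_bmi = TRUE)
  expect_equal(r1$beta, r0$beta, tolerance = 0.02)
  expect_equal(r1$model, "bmi_adjusted")
})

test_that("metabolome-wide screen returns one record per metabolite-lipid pair", {
  sim <- simulate_twin_cohort(twin_cohort_spec(n_pairs = 80, seed = 70))
  mm <- simulate_metabolome(sim, metabolome_spec(
    n_metabolites = 6, lod_quantile = 0, frac_high_cv = 0,
    frac_low_occurrence = 0))
  z <- transform_metabolites(mm)
  co <- transform_traits(sim$cohort)
  out <- associate(co, z, lipids = c("TG", "HDL_C"))
  expect_equal(nrow(out), 12L)
  expect_true(all(c("q_value", "significant") %in% names(out)))
  expect_true(all(out$q_value >= out$p_value - 1e-12))
})
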