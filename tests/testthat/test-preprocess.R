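test_that("analytical CV matches hand arithmetic and handles degenerate inputs", {
  qc <- cbind(flat = c(5, 5, 5), spread = c(1, 2, 3), short = c(2, NA, NA),
              zero = c(0, 0, 0))
  cv <- compute_cv(qc)
  expect_equal(unname(cv["flat"]), 0)
  expect_equal(unname(cv["spread"]), 0.5)  # sample SD 1 / mean 2
  expect_true(is.na(cv["short"]))          # < 2 detected values
  expect_true(is.na(cv["zero"]))           # non-positive mean
})

test_that("QC thresholds are strict: above 30% CV and below 50% occurrence", {
  # three values c(m - s, m, m + s) have sample SD s (n-1 denominator),
  # so the column's CV is exactly s / m
  col_cv <- function(cv) { m <- 10; c(m - cv * m, m, m + cv * m) }
  qc <- cbind(just_over = col_cv(0.31), just_under = col_cv(0.29),
              at_threshold = col_cv(0.30))
  rep_qc <- qc_report(qc)
  expect_equal(rep_qc$verdict[rep_qc$metabolite == "just_over"], "excluded_cv")
  expect_equal(rep_qc$verdict[rep_qc$metabolite == "just_under"], "kept")
  expect_equal(rep_qc$verdict[rep_qc$metabolite == "at_threshold"], "kept")

  # occurrence exactly 0.50 is kept ("below 50%" is strict)
  qc2 <- cbind(half = c(10, 11, NA, NA), low = c(10, NA, NA, NA),
               full = c(10, 11, 10, 11))
  rep2 <- qc_report(qc2)
  expect_equal(rep2$occurrence[rep2$metabolite == "half"], 0.5)
  expect_equal(rep2$verdict[rep2$metabolite == "half"], "kept")
  expect_equal(rep2$verdict[rep2$metabolite == "low"], "excluded_cv")
  expect_equal(rep2$verdict[rep2$metabolite == "full"], "kept")
  # verdict counts conserve the panel size
  expect_equal(sum(attr(rep2, "counts")), ncol(qc2))
})

test_that("filtering preserves metabolite order and is an identity when all pass", {
  qc <- matrix(rep(c(10, 10.5, 9.5), 4), 3, 4,
               dimnames = list(NULL, paste0("m", 1:4)))
  rep_qc <- qc_report(qc)
  expect_equal(filter_metabolites(rep_qc), paste0("m", 1:4))
})

test_that("LOD imputation substitutes the observed minimum and nothing else", {
  mm <- toy_metabolome(cbind(a = c(2.1, 0.5, 3.4), b = c(1, 2, 3)),
                       below = cbind(a = c(FALSE, TRUE, FALSE),
                                     b = rep(FALSE, 3)))
  mm$concentrations[2, "a"] <- NA  # censored cell
  out <- impute_lod(mm)
  expect_equal(unname(out$concentrations[, "a"]), c(2.1, 2.1, 3.4))
  expect_equal(unname(out$concentrations[, "b"]), c(1, 2, 3))  # untouched
  expect_equal(attr(out$concentrations, "n_imputed"), 1L)

  # no flags -> identity
  mm2 <- toy_metabolome(cbind(a = c(2, 3, 4)))
  expect_equal(impute_lod(mm2)$concentrations[, "a"],
               mm2$concentrations[, "a"])

  # all values below LOD -> no observed minimum exists
  mm3 <- toy_metabolome(cbind(a = rep(NA_real_, 3)),
                        below = cbind(a = rep(TRUE, 3)))
  expect_error(impute_lod(mm3), "no detected values")
})

test_that("imputation preserves each metabolite's observed minimum (property)", {
  set.seed(99)
  for (rep_i in 1:5) {
    sim <- simulate_twin_cohort(twin_cohort_spec(n_pairs = 30,
                                                 seed = 100 + rep_i))
    mm <- simulate_metabolome(sim, metabolome_spec(
      n_metabolites = 20, lod_quantile = 0.1, frac_high_cv = 0,
      frac_low_occurrence = 0, seed = rep_i))
    pre_min <- apply(mm$concentrations, 2, min, na.rm = TRUE)
    post <- impute_lod(mm)$concentrations
    expect_false(anyNA(post))
    expect_equal(apply(post, 2, min), pre_min)
  }
})

test_that("log + z-score transform matches the sample-SD convention", {
  # two individuals at e and e^3: logs (1, 3), mean 2, sample SD sqrt(2)
  mm <- toy_metabolome(cbind(a = c(exp(1), exp(3))))
  z <- transform_metabolites(mm)
  expect_equal(unname(z[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  sim <- simulate_twin_cohort(twin_cohort_spec(n_pairs = 50, seed = 21))
  mmx <- simulate_metabolome(sim, metabolome_spec(
    n_metabolites = 10, lod_quantile = 0.05, frac_high_cv = 0,
    frac_low_occurrence = 0, seed = 22))
  z2 <- transform_metabolites(impute_lod(mmx))
  expect_lt(max(abs(colMeans(z2))), 1e-10)
  expect_equal(unname(apply(z2, 2, sd)), rep(1, 10), tolerance = 1e-10)

  # degenerate constant column is NA-guarded with a warning
  expect_warning(zc <- transform_metabolites(toy_metabolome(
    cbind(a = c(2, 2, 2), b = c(1, 2, 4)))), "degenerate")
  expect_true(all(is.na(zc[, "a"])))
  expect_equal(attr(zc, "degenerate"), "a")
  # non-positive values are an error naming the metabolite
  expect_error(transform_metabolites(toy_metabolome(cbind(bad = c(1, -1, 2)))),
               "bad")
})

test_that("trait transform logs the right traits and propagates missingness", {
  co <- data.frame(TG = c(1.0, 2.0, NA), SBP = c(120, 140, 130),
                   DBP = c(80, 90, 85), HDL_C = c(1.2, 1.4, 1.3))
  out <- transform_traits(co)
  expect_equal(out$TG, c(0, log(2), NA))
  expect_equal(out$SBP, co$SBP)   # blood pressure stays on the raw scale
  expect_equal(out$DBP, co$DBP)
  expect_equal(out$HDL_C, log(co$HDL_C))
  # completeness report mirrors injected missingness
  cr <- completeness_report(co)
  expect_equal(cr$n_missing[cr$trait == "TG"], 1L)
  # non-positive trait values become missing with a logged count
  co2 <- data.frame(TG = c(1, 0, 2))
  out2 <- transform_traits(co2)
  expect_true(is.na(out2$TG[2]))
  expect_equal(unname(attr(out2, "n_nonpositive")["TG"]), 1L)
})

test_that("preprocessing is idempotent and conserves the panel", {
  sim <- simulate_twin_cohort(twin_cohort_spec(n_pairs = 40, seed = 55))
  mm <- simulate_metabolome(sim, metabolome_spec(
    n_metabolites = 50, lod_quantile = 0.04, frac_high_cv = 0.2,
    frac_low_occurrence = 0.1, seed = 56))
  rep_qc <- qc_report(mm)
  kept <- apply_qc_filter(mm, rep_qc)
  # conservation: kept + excluded = assayed
  cnt <- attr(rep_qc, "counts")
  expect_equal(sum(cnt), 50L)
  expect_equal(ncol(kept$concentrations), unname(cnt["kept"]))
  # idempotence: filtering the filtered panel changes nothing
  kept2 <- apply_qc_filter(kept, qc_report(kept))
  expect_identical(kept2$concentrations, kept$concentrations)
  imp <- impute_lod(kept)
  imp2 <- impute_lod(imp)
  expect_equal(imp2$concentrations[, ], imp$concentrations[, ])
})
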