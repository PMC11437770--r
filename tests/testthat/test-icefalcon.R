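test_that("co-twin design keeps complete pairs only and is role-exchange closed", {
  sim <- simulate_twin_cohort(twin_cohort_spec(n_pairs = 210, n_singletons = 17,
                                               missing_counts = NULL, seed = 4))
  co <- transform_traits(sim$cohort)
  co$met <- rnorm(nrow(co))
  des <- build_cotwin_design(co, "TG", "met")
  expect_equal(nrow(des), 420L)               # singletons never enter
  expect_equal(attr(des, "n_pairs"), 210L)

  # a pair with one missing predictor contributes no rows
  co2 <- co
  co2$TG[which(co2$pair_id == co2$pair_id[1])[1]] <- NA
  des2 <- build_cotwin_design(co2, "TG", "met")
  expect_equal(nrow(des2), 418L)

  # role exchange: swapping twin labels yields the same row multiset
  co3 <- co[with(co, ave(seq_along(pair_id), pair_id,
                         FUN = function(i) rev(i))), ]
  des3 <- build_cotwin_design(co3, "TG", "met")
  key <- function(d) sort(paste(d$y_self, d$x_self, d$x_cotwin))
  expect_equal(key(des3), key(des))

  expect_error(build_cotwin_design(co[1:40, ], "TG", "met"), "usable")
})

test_that("coefficient change is conditional minus marginal", {
  expect_equal(coefficient_change(0.25, 0.25), 0)
  expect_equal(coefficient_change(0.0546, 0.1230), 0.0684)
  expect_equal(coefficient_change(0.1978, 0.0853), -0.1125)
  expect_error(coefficient_change(NA, 1))
})

test_that("three-model fits follow the structural-model expectations", {
  # causal scenario (heritable lipid causes the metabolite):
  # beta_self ~ beta, beta_cotwin ~ beta * lambda_x^2, bprime_cotwin ~ 0,
  # bprime_self ~ beta_self (no attenuation of the self coefficient)
  dat <- scenario_data(31, "causal", n_pairs = 5000)
  des <- build_cotwin_design(dat, "lipid_z", "met_z")
  tri <- fit_three_models(des)
  est <- tri$coefs$estimate
  expect_equal(est[1], 0.30, tolerance = 0.05)          # beta_self
  expect_gt(est[2] / tri$coefs$se[2], 4)                # beta_cotwin > 0
  expect_equal(est[2], 0.3 * 0.49, tolerance = 0.05)
  expect_lt(abs(est[4]), 0.05)                          # bprime_cotwin ~ 0
  expect_lt(abs(tri$change_self), 0.04)                 # self unchanged
  # arithmetic identity of the stored changes
  expect_identical(tri$change_self, est[3] - est[1])
  expect_identical(tri$change_cotwin, est[4] - est[2])

  # confounding-only: both Model-3 coefficients attenuate. Note the marginal
  # GEE estimand under an omitted shared confounder is (m - rho*c)/(1 - rho*rx),
  # below the OLS marginal correlation m = 0.49, so only a range is asserted.
  datc <- scenario_data(32, "confounding", n_pairs = 5000)
  tric <- fit_three_models(build_cotwin_design(datc, "lipid_z", "met_z"))
  expect_lt(tric$change_self, -0.05)
  expect_lt(tric$change_cotwin, -0.05)
  expect_gt(tric$coefs$estimate[1], 0.3)
  expect_lt(tric$coefs$p[1], 1e-10)

  # independence: all six coefficients near zero
  dati <- scenario_data(33, "independent", n_pairs = 3000)
  trii <- fit_three_models(build_cotwin_design(dati, "lipid_z", "met_z"))
  expect_lt(max(abs(trii$coefs$estimate)), 0.06)

  # constant predictor is a singular design
  datx <- dat
  datx$lipid_z <- 1
  expect_error(fit_three_models(build_cotwin_design(datx, "lipid_z", "met_z")),
               "constant")
})

test_that("pair bootstrap is reproducible and degenerate designs are flagged", {
  dat <- scenario_data(41, "causal", n_pairs = 200)
  des <- build_cotwin_design(dat, "lipid_z", "met_z")
  tri <- fit_three_models(des)
  b1 <- bootstrap_changes(des, B = 50, seed = 7, triplet = tri)
  b2 <- bootstrap_changes(des, B = 50, seed = 7, triplet = tri)
  expect_identical(b1[c("se_change_self", "se_change_cotwin",
                        "p_change_self", "p_change_cotwin")],
                   b2[c("se_change_self", "se_change_cotwin",
                        "p_change_self", "p_change_cotwin")])
  b3 <- bootstrap_changes(des, B = 50, seed = 8, triplet = tri)
  expect_false(identical(b1$se_change_cotwin, b3$se_change_cotwin))
  expect_equal(b1$B, 50L)

  # an outcome with no variation gives identically-zero coefficients in every
  # resample: zero bootstrap variance, flagged degenerate
  set.seed(9)
  dg <- data.frame(pair_id = rep(sprintf("p%02d", 1:40), each = 2),
                   twin_index = rep(1:2, 40),
                   x = rnorm(80), y = rep(0, 80))
  desg <- build_cotwin_design(dg, "x", "y")
  trig <- fit_three_models(desg, rho = 0)
  bg <- bootstrap_changes(desg, B = 20, seed = 1, triplet = trig, rho = 0)
  expect_true(bg$degenerate)
  expect_true(is.na(bg$p_change_cotwin))
})

test_that("one-sided change P is directional: attenuation vs observed", {
  # positive marginal, negative change -> small attenuation P;
  # positive change (away from the null) -> attenuation P near 1
  p_att <- twinfalcon:::.change_p(-0.3, 0.1, marginal = 0.5, "attenuation")
  expect_equal(p_att, pnorm(-3))
  p_away <- twinfalcon:::.change_p(0.3, 0.1, marginal = 0.5, "attenuation")
  expect_equal(p_away, pnorm(3))
  # observed-direction convention is sign-agnostic
  expect_equal(twinfalcon:::.change_p(0.3, 0.1, 0.5, "observed"), pnorm(-3))
  expect_equal(twinfalcon:::.change_p(-0.3, 0.1, 0.5, "observed"), pnorm(-3))
  # negative marginal mirrors
  expect_equal(twinfalcon:::.change_p(0.3, 0.1, -0.5, "attenuation"), pnorm(-3))
})

test_that("bidirectional run classifies the three canonical scenarios", {
  dat <- scenario_data(51, "causal", n_pairs = 1000)
  res <- ice_falcon(dat, "TG", "met", B = 200, seed = 3)
  expect_s3_class(res, "falcon_result")
  expect_equal(res$classification, "consistent_causal_X_to_Y")

  # swapping the arguments exchanges the triplets and flips the label
  res_sw <- ice_falcon(dat, "met", "TG", B = 200, seed = 3)
  expect_equal(res_sw$classification, "consistent_causal_Y_to_X")
  expect_equal(res_sw$directions$y_as_predictor$triplet$coefs$estimate,
               res$directions$x_as_predictor$triplet$coefs$estimate)

  datc <- scenario_data(52, "confounding", n_pairs = 1000)
  resc <- ice_falcon(datc, "TG", "met", B = 200, seed = 4)
  expect_equal(resc$classification, "consistent_familial_confounding")

  dati <- scenario_data(53, "independent", n_pairs = 1000)
  resi <- ice_falcon(dati, "TG", "met", B = 200, seed = 5)
  expect_equal(resi$classification, "inconclusive")

  # classification is a pure function of the stored numbers
  expect_equal(classify_pattern(res, alpha = res$alpha), res$classification)
  tab <- as.data.frame(res)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$change_cotwin[1],
               res$directions$x_as_predictor$triplet$change_cotwin)
})
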