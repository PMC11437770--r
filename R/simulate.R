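#' Specification for a synthetic MZ-twin cohort
#'
#' Describes the structural model used by [simulate_twin_cohort()]. Each family
#' (twin pair, or singleton) carries one standard-normal familial confounder
#' `C`. Two standardized latent traits are generated per individual:
#'
#' \deqn{X = \lambda_x C + \epsilon_x, \qquad
#'       Y = \beta X + \lambda_y C + \sum_k \gamma_k Z_k + \epsilon_y}
#'
#' (the causal term is reversed for `causal_direction = "y_to_x"` and absent
#' for `"none"`). Residual standard deviations default to whatever completes a
#' unit variance; if supplied, the trait is renormalized to unit variance. `X`
#' is mapped onto the target lipid (log-normal scale) and `Y` is exposed to the
#' metabolome generator as the "structural" metabolite.
#'
#' @param n_pairs Number of complete MZ pairs (default 210).
#' @param n_singletons Number of unrelated individuals (default 17).
#' @param familial_loading_x,familial_loading_y Path coefficients in `[0, 1]`
#'   from the shared familial confounder to the latent traits.
#' @param causal_effect Standardized causal effect between the latent traits.
#' @param causal_direction One of `"x_to_y"`, `"y_to_x"`, `"none"`.
#' @param noise_sd_x,noise_sd_y Residual SDs; `NULL` (default) completes the
#'   variance to 1, otherwise the trait is renormalized.
#' @param covariate_effects Named numeric vector of standardized effects of
#'   covariates (`age`, `gender`, `region`, `survey_year`, `BMI`) on `Y`.
#' @param target_lipid Cohort lipid column carrying the latent `X`
#'   (default `"TG"`).
#' @param missing_counts Named integer vector of missing values to inject per
#'   trait (defaults mirror a real co-resident MZ cohort: TG 1, BMI 4,
#'   HbA1c 36, HOMA_IR 6).
#' @param seed Master integer seed.
#'
#' @return An object of class `twin_cohort_spec`.
#' @seealso [simulate_twin_cohort()]
#' @export
twin_cohort_spec <- function(n_pairs = 210L, n_singletons = 17L,
                             familial_loading_x = 0.7,
                             familial_loading_y = 0,
                             causal_effect = 0.3,
                             causal_direction = c("x_to_y", "y_to_x", "none"),
                             noise_sd_x = NULL, noise_sd_y = NULL,
                             covariate_effects = NULL,
                             target_lipid = "TG",
                             missing_counts = c(TG = 1L, BMI = 4L,
                                                HbA1c = 36L, HOMA_IR = 6L),
                             seed = 1L) {
  causal_direction <- match.arg(causal_direction)
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 1)
    stop("`n_pairs` must be a positive integer")
  if (!is.numeric(n_singletons) || n_singletons < 0)
    stop("`n_singletons` must be a non-negative integer")
  for (nm in c("familial_loading_x", "familial_loading_y")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must lie in [0, 1], got %s", nm, format(v)))
  }
  if (!is.null(noise_sd_x) && noise_sd_x <= 0)
    stop("`noise_sd_x` must be positive")
  if (!is.null(noise_sd_y) && noise_sd_y <= 0)
    stop("`noise_sd_y` must be positive")
  if (!is.null(covariate_effects)) {
    if (is.null(names(covariate_effects)) ||
        !all(names(covariate_effects) %in% c(.COVARIATES, "BMI")))
      stop("`covariate_effects` must be named with covariates among: ",
           paste(c(.COVARIATES, "BMI"), collapse = ", "))
  }
  if (!target_lipid %in% .LIPIDS)
    stop("`target_lipid` must be one of: ", paste(.LIPIDS, collapse = ", "))
  spec <- list(n_pairs = as.integer(n_pairs),
               n_singletons = as.integer(n_singletons),
               familial_loading_x = familial_loading_x,
               familial_loading_y = familial_loading_y,
               causal_effect = causal_effect,
               causal_direction = causal_direction,
               noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
               covariate_effects = covariate_effects,
               target_lipid = target_lipid,
               missing_counts = missing_counts,
               seed = as.integer(seed))
  # Validate the variance budget up-front so misconfiguration fails loudly.
  .variance_budget(spec)
  class(spec) <- "twin_cohort_spec"
  spec
}

# Returns the residual variance left for the downstream trait; errors if the
# structural contributions already exceed unit variance.
.variance_budget <- function(spec) {
  lx <- spec$familial_loading_x
  ly <- spec$familial_loading_y
  b <- spec$causal_effect
  # effective loading of the standardized upstream trait on C
  sd_up <- if (spec$causal_direction == "y_to_x") {
    if (is.null(spec$noise_sd_y)) 1 else sqrt(ly^2 + spec$noise_sd_y^2)
  } else {
    if (is.null(spec$noise_sd_x)) 1 else sqrt(lx^2 + spec$noise_sd_x^2)
  }
  l_up <- switch(spec$causal_direction,
                 x_to_y = lx / sd_up, y_to_x = ly / sd_up, none = 0)
  l_down <- switch(spec$causal_direction,
                   x_to_y = ly, y_to_x = lx, none = max(lx, ly))
  gam2 <- sum(spec$covariate_effects^2)
  used <- if (spec$causal_direction == "none") {
    ly^2 + gam2
  } else {
    b^2 + l_down^2 + 2 * b * l_up * l_down + gam2
  }
  if (used >= 1 && (is.null(spec$noise_sd_x) || is.null(spec$noise_sd_y)))
    stop(sprintf(paste0(
      "variance budget exceeded (%.3f >= 1): reduce causal_effect, ",
      "familial_loading_x/familial_loading_y or covariate_effects, ",
      "or supply explicit noise SDs"), used))
  max(1 - used, 0)
}

# Table-style reference scales for trait generation: location / spread on the
# scale the trait is measured (log-normal for all but SBP/DBP).
.TRAIT_SCALES <- list(
  TG      = list(log = TRUE,  mu = log(1.46),   sigma = 0.535),
  TC      = list(log = TRUE,  mu = log(4.88),   sigma = 0.199),
  LDL_C   = list(log = TRUE,  mu = log(2.59),   sigma = 0.286),
  HDL_C   = list(log = TRUE,  mu = log(1.24),   sigma = 0.276),
  GLU     = list(log = TRUE,  mu = log(5.53),   sigma = 0.218),
  HbA1c   = list(log = TRUE,  mu = log(5.70),   sigma = 0.114),
  HOMA_IR = list(log = TRUE,  mu = log(1.94),   sigma = 0.768),
  SBP     = list(log = FALSE, mu = 142.95,      sigma = 21.36),
  DBP     = list(log = FALSE, mu = 87.58,       sigma = 12.48),
  UA      = list(log = TRUE,  mu = log(327.25), sigma = 0.264),
  hsCRP   = list(log = TRUE,  mu = log(0.99),   sigma = 0.877)
)

#' Simulate an MZ-twin cohort with known causal structure
#'
#' Generates a long-format cohort (one row per individual) of `n_pairs`
#' complete MZ pairs plus `n_singletons` unrelated individuals, with
#' pair-shared covariates (age, gender, region, survey year), an individual
#' BMI with a pair-shared component, four lipid parameters and seven
#' cardiometabolic traits on realistic scales, and a latent structural pair
#' `(X, Y)` following the model described in [twin_cohort_spec()]. The latent
#' truth (familial confounder, latent traits, true effect) is returned as a
#' separate `truth` table so downstream analyses cannot accidentally use it.
#'
#' @param spec A [twin_cohort_spec()].
#' @return An object of class `twin_cohort_sim`: a list with elements
#'   `cohort` (data.frame), `truth` (data.frame) and `spec`.
#' @examples
#' sim <- simulate_twin_cohort(twin_cohort_spec(n_pairs = 50, seed = 7))
#' nrow(sim$cohort)  # 2 * 50 + 17
#' @export
simulate_twin_cohort <- function(spec = twin_cohort_spec()) {
  stopifnot(inherits(spec, "twin_cohort_spec"))
  set.seed(.substream(spec$seed, 101L))
  np <- spec$n_pairs; ns <- spec$n_singletons
  n_fam <- np + ns
  n <- 2L * np + ns
  # family index per row: pairs first (two rows each), then singletons
  fam <- c(rep(seq_len(np), each = 2L), if (ns > 0) np + seq_len(ns))
  twin_index <- c(rep(1:2, np), if (ns > 0) rep(1L, ns))
  pair_id <- sprintf("fam%04d", fam)
  individual_id <- sprintf("ind%04d", seq_len(n))

  ## pair-shared covariates
  age_f <- round(stats::rnorm(n_fam, 52.05, 10.05), 1)
  gender_f <- ifelse(stats::runif(n_fam) < 0.307, "female", "male")
  region_f <- ifelse(stats::runif(n_fam) < 0.746, "southern", "northern")
  year_f <- ifelse(stats::runif(n_fam) < 0.5, 2013L, 2018L)
  age <- age_f[fam]; gender <- gender_f[fam]
  region <- region_f[fam]; survey_year <- year_f[fam]
  # BMI: pair-shared + individual component, mean 25.08, sd 3.34
  bmi_f <- stats::rnorm(n_fam, 0, sqrt(0.5))
  BMI <- round(25.08 + 3.34 * (bmi_f[fam] + stats::rnorm(n, 0, sqrt(0.5))), 2)

  ## structural latents
  C <- stats::rnorm(n_fam)[fam]              # familial confounder, pair-shared
  lx <- spec$familial_loading_x; ly <- spec$familial_loading_y
  b <- spec$causal_effect
  std <- function(lin, loading, noise_sd) {
    if (is.null(noise_sd)) {
      resid_var <- 1 - loading
      if (resid_var <= 0)
        stop("variance budget exceeded for a latent trait; ",
             "check familial loadings, causal_effect and covariate_effects")
      lin + stats::rnorm(n, 0, sqrt(resid_var))
    } else {
      (lin + stats::rnorm(n, 0, noise_sd)) / sqrt(loading + noise_sd^2)
    }
  }
  cov_term <- 0
  if (!is.null(spec$covariate_effects)) {
    covs <- list(age = age, gender = as.numeric(gender == "female"),
                 region = as.numeric(region == "southern"),
                 survey_year = as.numeric(survey_year == 2018L), BMI = BMI)
    for (nm in names(spec$covariate_effects)) {
      v <- covs[[nm]]
      cov_term <- cov_term + spec$covariate_effects[[nm]] *
        (v - mean(v)) / stats::sd(v)
    }
  }
  gam2 <- sum(spec$covariate_effects^2)
  if (spec$causal_direction == "x_to_y") {
    x <- std(lx * C, lx^2, spec$noise_sd_x)
    l_up <- if (is.null(spec$noise_sd_x)) lx else lx / sqrt(lx^2 + spec$noise_sd_x^2)
    lin_y <- b * x + ly * C + cov_term
    y <- std(lin_y, b^2 + ly^2 + 2 * b * l_up * ly + gam2, spec$noise_sd_y)
  } else if (spec$causal_direction == "y_to_x") {
    y <- std(ly * C + cov_term, ly^2 + gam2, spec$noise_sd_y)
    l_up <- if (is.null(spec$noise_sd_y)) ly else ly / sqrt(ly^2 + spec$noise_sd_y^2)
    lin_x <- b * y + lx * C
    x <- std(lin_x, b^2 + lx^2 + 2 * b * l_up * lx, spec$noise_sd_x)
  } else {
    x <- std(lx * C, lx^2, spec$noise_sd_x)
    y <- std(ly * C + cov_term, ly^2 + gam2, spec$noise_sd_y)
  }

  ## traits: target lipid carries X; the rest are independent with their own
  ## pair-shared familial component (loading sqrt(0.5))
  cohort <- data.frame(individual_id = individual_id, pair_id = pair_id,
                       twin_index = twin_index, age = age, gender = gender,
                       region = region, survey_year = survey_year, BMI = BMI,
                       stringsAsFactors = FALSE)
  for (tr in c(.LIPIDS, .CM_TRAITS)) {
    sc <- .TRAIT_SCALES[[tr]]
    z <- if (tr == spec$target_lipid) {
      x
    } else {
      Ft <- stats::rnorm(n_fam)[fam]
      sqrt(0.5) * Ft + stats::rnorm(n, 0, sqrt(0.5))
    }
    v <- if (sc$log) exp(sc$mu + sc$sigma * z) else sc$mu + sc$sigma * z
    cohort[[tr]] <- round(v, 4)
  }

  ## inject missingness
  mc <- spec$missing_counts
  for (nm in names(mc)) {
    k <- min(as.integer(mc[[nm]]), n)
    if (k > 0 && nm %in% names(cohort))
      cohort[[nm]][sample.int(n, k)] <- NA_real_
  }

  truth <- data.frame(individual_id = individual_id, pair_id = pair_id,
                      familial_confounder = C, x_latent = x, y_latent = y,
                      causal_effect = spec$causal_effect,
                      causal_direction = spec$causal_direction,
                      stringsAsFactors = FALSE)
  structure(list(cohort = cohort, truth = truth, spec = spec),
            class = "twin_cohort_sim")
}

#' @export
print.twin_cohort_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic MZ twin cohort: %d individuals (%d pairs + %d singletons)\n",
    nrow(x$cohort), x$spec$n_pairs, x$spec$n_singletons))
  cat(sprintf("Causal structure: %s (beta = %.3g, loadings x = %.2g, y = %.2g)\n",
              x$spec$causal_direction, x$spec$causal_effect,
              x$spec$familial_loading_x, x$spec$familial_loading_y))
  invisible(x)
}

#' Specification for a synthetic targeted metabolome
#'
#' Describes the metabolite panel generated by [simulate_metabolome()]:
#' log-normal concentrations, a structural metabolite carrying the cohort's
#' latent `Y`, optional extra metabolites wired to the target lipid and/or the
#' familial confounder, below-LOD censoring, and a QC-replicate matrix with
#' planted analytical-CV and occurrence failures.
#'
#' QC verdicts are planted deterministically: replicate values are rescaled so
#' each metabolite's sample CV equals its target exactly, high-CV targets are
#' drawn above the 30% filter and low-occurrence metabolites get fewer than
#' half of the replicates detected, with the two failure sets disjoint. The
#' defaults (350 assayed, 20% high-CV, 9.1% low-occurrence) leave 248
#' metabolites after filtering.
#'
#' @param n_metabolites Number of metabolites assayed (default 350).
#' @param lod_quantile Fraction of each metabolite's study-sample values
#'   censored below the detection limit (default 0.02; must be `< 1`).
#' @param qc_replicates Number of QC injections (default 10; must be >= 2).
#' @param cv_range Length-2 target analytical CV range for passing metabolites
#'   (default `c(0.05, 0.15)`).
#' @param frac_high_cv Fraction of metabolites planted with CV above the 30%
#'   filter (default 0.2).
#' @param frac_low_occurrence Fraction planted with QC occurrence below 50%
#'   (default 0.091).
#' @param structural_metabolite Index of the metabolite whose latent equals the
#'   cohort's structural `Y` (`NA` to disable; default 1).
#' @param wiring Optional data.frame with columns `metabolite` (index), `beta`
#'   (loading on the standardized log target lipid) and `loading` (on the
#'   familial confounder) for additional wired metabolites.
#' @param gut_fraction Fraction flagged as gut-microbiota-derived
#'   (default 0.62, i.e. roughly 154 of 248).
#' @param seed Integer seed (defaults to the cohort's sub-stream at
#'   generation time if `NULL`).
#' @return An object of class `metabolome_spec`.
#' @export
metabolome_spec <- function(n_metabolites = 350L, lod_quantile = 0.02,
                            qc_replicates = 10L, cv_range = c(0.05, 0.15),
                            frac_high_cv = 0.2, frac_low_occurrence = 0.091,
                            structural_metabolite = 1L, wiring = NULL,
                            gut_fraction = 0.62, seed = NULL) {
  if (n_metabolites < 1) stop("`n_metabolites` must be positive")
  if (lod_quantile < 0 || lod_quantile >= 1)
    stop("`lod_quantile` must lie in [0, 1)")
  if (qc_replicates < 2) stop("`qc_replicates` must be at least 2")
  if (length(cv_range) != 2L || any(cv_range <= 0) || cv_range[1] > cv_range[2])
    stop("`cv_range` must be an increasing pair of positive fractions")
  if (frac_high_cv < 0 || frac_high_cv > 1 ||
      frac_low_occurrence < 0 || frac_low_occurrence > 1 ||
      frac_high_cv + frac_low_occurrence > 1)
    stop("`frac_high_cv` and `frac_low_occurrence` must be fractions summing to at most 1")
  if (!is.null(wiring)) {
    stopifnot(is.data.frame(wiring),
              all(c("metabolite", "beta", "loading") %in% names(wiring)))
    if (any(wiring$metabolite < 1 | wiring$metabolite > n_metabolites))
      stop("`wiring$metabolite` indices out of range")
  }
  structure(list(n_metabolites = as.integer(n_metabolites),
                 lod_quantile = lod_quantile,
                 qc_replicates = as.integer(qc_replicates),
                 cv_range = cv_range, frac_high_cv = frac_high_cv,
                 frac_low_occurrence = frac_low_occurrence,
                 structural_metabolite = structural_metabolite,
                 wiring = wiring, gut_fraction = gut_fraction, seed = seed),
            class = "metabolome_spec")
}

.MET_CLASSES <- c("amino acids", "benzenoids", "bile acids", "carbohydrates",
                  "carnitines", "fatty acids", "indoles", "organic acids",
                  "phenylpropanoic acids", "pyridines", "nucleosides",
                  "amines", "alcohols", "peptides", "others")

#' Simulate a targeted metabolome with QC replicates and LOD censoring
#'
#' Builds an individuals-by-metabolites concentration matrix on the log-normal
#' scale, flags the lowest `lod_quantile` fraction of each metabolite's values
#' as below the limit of detection (their concentrations are set to `NA`), and
#' generates a QC-replicate matrix with deterministically planted CV and
#' occurrence failures (see [metabolome_spec()]).
#'
#' @param sim A `twin_cohort_sim` from [simulate_twin_cohort()] (the latent
#'   truth is used only to wire metabolites to the structural model).
#' @param spec A [metabolome_spec()].
#' @return An object of class `metabolite_matrix`: a list with
#'   `concentrations` (matrix, `NA` where below LOD), `below_lod` (logical
#'   matrix), `qc` (QC injections x metabolites, `NA` = not detected),
#'   `meta` (metabolite, class, gut_microbiota) and `qc_truth` (planted
#'   verdicts and target CVs).
#' @export
simulate_metabolome <- function(sim, spec = metabolome_spec()) {
  stopifnot(inherits(sim, "twin_cohort_sim"), inherits(spec, "metabolome_spec"))
  cohort <- sim$cohort
  if (nrow(cohort) == 0L) stop("cohort is empty")
  seed <- if (is.null(spec$seed)) .substream(sim$spec$seed, 202L) else spec$seed
  set.seed(seed)
  n <- nrow(cohort); M <- spec$n_metabolites
  ids <- cohort$individual_id
  mets <- sprintf("met%03d", seq_len(M))

  # latent X equals the standardized log target lipid (pre-missingness)
  x_std <- sim$truth$x_latent
  C <- sim$truth$familial_confounder
  y_std <- sim$truth$y_latent

  mu <- stats::runif(M, log(0.1), log(100))
  sigma <- stats::runif(M, 0.3, 0.8)
  Z <- matrix(stats::rnorm(n * M), n, M)
  if (!is.na(spec$structural_metabolite))
    Z[, spec$structural_metabolite] <- y_std
  if (!is.null(spec$wiring)) {
    for (k in seq_len(nrow(spec$wiring))) {
      w <- spec$wiring[k, ]
      lx_eff <- sim$spec$familial_loading_x
      resid <- 1 - w$beta^2 - w$loading^2 - 2 * w$beta * w$loading * lx_eff
      if (resid <= 0)
        stop(sprintf("wiring for metabolite %d exceeds unit variance",
                     w$metabolite))
      Z[, w$metabolite] <- w$beta * x_std + w$loading * C +
        stats::rnorm(n, 0, sqrt(resid))
    }
  }
  conc <- exp(sweep(sweep(Z, 2, sigma, `*`), 2, mu, `+`))
  dimnames(conc) <- list(ids, mets)

  # below-LOD censoring: lowest floor(q * n) values per metabolite
  below <- matrix(FALSE, n, M, dimnames = dimnames(conc))
  k_cens <- floor(spec$lod_quantile * n)
  if (k_cens > 0) {
    for (j in seq_len(M)) {
      idx <- order(conc[, j])[seq_len(k_cens)]
      below[idx, j] <- TRUE
      conc[idx, j] <- NA_real_
    }
  }

  # QC matrix with planted verdicts (disjoint failure sets)
  R <- spec$qc_replicates
  n_high <- round(spec$frac_high_cv * M)
  n_low <- round(spec$frac_low_occurrence * M)
  fail_idx <- sample.int(M, n_high + n_low)
  high_cv_idx <- fail_idx[seq_len(n_high)]
  low_occ_idx <- setdiff(fail_idx, high_cv_idx)
  target_cv <- stats::runif(M, spec$cv_range[1], spec$cv_range[2])
  target_cv[high_cv_idx] <- stats::runif(n_high, 0.35, 0.60)
  occ_k <- rep(R, M)
  if (n_low > 0)
    occ_k[low_occ_idx] <- pmax(2L, floor(R * stats::runif(n_low, 0.15, 0.45)))
  qc <- matrix(NA_real_, R, M, dimnames = list(sprintf("QC%02d", seq_len(R)),
                                               mets))
  for (j in seq_len(M)) {
    k <- occ_k[j]
    raw <- exp(mu[j] + stats::rnorm(k, 0, 0.2))
    m0 <- mean(raw)
    zhat <- if (stats::sd(raw) > 0) (raw - m0) / stats::sd(raw) else rep(0, k)
    vals <- m0 * (1 + target_cv[j] * zhat)  # sample CV == target exactly
    qc[seq_len(k), j] <- vals
  }

  classes <- sample(.MET_CLASSES, M, replace = TRUE,
                    prob = c(0.25, 0.05, 0.06, 0.05, 0.08, 0.12, 0.03, 0.12,
                             0.02, 0.03, 0.04, 0.04, 0.03, 0.04, 0.04))
  meta <- data.frame(metabolite = mets, class = classes,
                     gut_microbiota = stats::runif(M) < spec$gut_fraction,
                     stringsAsFactors = FALSE)
  verdict <- rep("kept", M)
  verdict[high_cv_idx] <- "excluded_cv"
  verdict[low_occ_idx] <- "excluded_occurrence"
  qc_truth <- data.frame(metabolite = mets, planted_verdict = verdict,
                         target_cv = target_cv, occurrence = occ_k / R,
                         stringsAsFactors = FALSE)
  structure(list(concentrations = conc, below_lod = below, qc = qc,
                 meta = meta, qc_truth = qc_truth, spec = spec),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("Metabolite matrix: %d individuals x %d metabolites\n",
              nrow(x$concentrations), ncol(x$concentrations)))
  cat(sprintf("QC replicates: %d; below-LOD cells: %d\n",
              nrow(x$qc), sum(x$below_lod)))
  invisible(x)
}

#' Simulate data for mediation analysis with planted indirect effects
#'
#' Generates one standardized exposure (a lipid-like trait) and, per triplet,
#' a mediator and an outcome following the linear structural model
#' `M = a E + e_M`, `O = b M + c' E + e_O`, so the true average causal
#' mediation effect is `a * b` and the true total effect `a * b + c'`.
#' Covariates (age, gender, region, survey year) are generated independent of
#' the structural variables, so adjusted and unadjusted fits agree in
#' expectation.
#'
#' @param n Number of individuals.
#' @param a,b,c_prime Path coefficients, recycled across triplets.
#' @param n_triplets Number of mediator/outcome pairs sharing the exposure.
#' @param seed Integer seed.
#' @return A data.frame with columns `exposure`, `mediator1..k`,
#'   `outcome1..k`, and covariates.
#' @export
simulate_mediation_data <- function(n, a = 0.5, b = 0.4, c_prime = 0.1,
                                    n_triplets = 1L, seed = 1L) {
  stopifnot(n > 0, n_triplets >= 1)
  set.seed(.substream(seed, 303L))
  a <- rep_len(a, n_triplets); b <- rep_len(b, n_triplets)
  c_prime <- rep_len(c_prime, n_triplets)
  E <- stats::rnorm(n)
  out <- data.frame(exposure = E)
  for (k in seq_len(n_triplets)) {
    Mv <- a[k] * E + stats::rnorm(n, 0, sqrt(max(1 - a[k]^2, 0.05)))
    Ov <- b[k] * Mv + c_prime[k] * E + stats::rnorm(n)
    out[[paste0("mediator", k)]] <- Mv
    out[[paste0("outcome", k)]] <- Ov
  }
  out$age <- round(stats::rnorm(n, 52.05, 10.05), 1)
  out$gender <- ifelse(stats::runif(n) < 0.307, "female", "male")
  out$region <- ifelse(stats::runif(n) < 0.746, "southern", "northern")
  out$survey_year <- ifelse(stats::runif(n) < 0.5, 2013L, 2018L)
  out
}
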