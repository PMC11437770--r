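#' Pair-clustered association between one metabolite and one lipid
#'
#' Regresses the (log-transformed) lipid on the standardized metabolite,
#' adjusting for age, gender, region and survey year as fixed effects and the
#' twin pair as a random intercept (the default `"lmm"` engine, fitted with
#' lme4). An exchangeable-correlation marginal model with robust SEs
#' (`"gee"` engine) is available as an equivalent backend. Singletons enter as
#' clusters of size 1. P values use the large-sample normal reference on
#' beta/se. Covariates that do not vary in the analysis sample are dropped.
#'
#' @param cohort Cohort data.frame (traits already transformed via
#'   [transform_traits()]), containing `pair_id` and covariates.
#' @param metabolite Either the name of a numeric column of `cohort` or a
#'   numeric vector aligned with its rows (standardized log-abundance).
#' @param lipid Lipid column name (`TG`, `TC`, `LDL_C`, `HDL_C`).
#' @param adjust_bmi Additionally adjust for BMI (sensitivity analysis).
#' @param engine `"lmm"` (random intercept, default) or `"gee"`.
#' @param reml Use REML for the `"lmm"` engine (default TRUE).
#' @param min_n Minimum complete cases (default 10).
#' @param metabolite_name Label used in the returned record.
#' @return One-row data.frame: `metabolite`, `lipid`, `beta`, `se`, `p_value`,
#'   `n`, `model`, `engine`, `converged`.
#' @export
fit_association <- function(cohort, metabolite, lipid, adjust_bmi = FALSE,
                            engine = c("lmm", "gee"), reml = TRUE,
                            min_n = 10L,
                            metabolite_name = NULL) {
  engine <- match.arg(engine)
  stopifnot(lipid %in% names(cohort), "pair_id" %in% names(cohort))
  if (is.character(metabolite) && length(metabolite) == 1L) {
    metabolite_name <- metabolite_name %||% metabolite
    met <- cohort[[metabolite]]
  } else {
    metabolite_name <- metabolite_name %||% "metabolite"
    met <- as.numeric(metabolite)
    stopifnot(length(met) == nrow(cohort))
  }
  covs <- .COVARIATES
  if (adjust_bmi) covs <- c(covs, "BMI")
  covs <- intersect(covs, names(cohort))
  dat <- data.frame(y = cohort[[lipid]], met = met,
                    pair_id = cohort$pair_id,
                    cohort[, covs, drop = FALSE],
                    stringsAsFactors = FALSE)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < min_n)
    stop(sprintf("only %d complete cases for %s vs %s (need >= %d)",
                 nrow(dat), metabolite_name, lipid, min_n))
  covs <- covs[vapply(covs, function(cv) length(unique(dat[[cv]])) > 1L,
                      logical(1))]
  rhs <- paste(c("met", covs), collapse = " + ")
  converged <- TRUE
  if (engine == "lmm") {
    fml <- stats::as.formula(paste0("y ~ ", rhs, " + (1 | pair_id)"))
    fit <- tryCatch(
      lme4::lmer(fml, data = dat, REML = reml,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)),
      warning = function(w) {
        converged <<- FALSE
        suppressWarnings(lme4::lmer(fml, data = dat, REML = reml,
                                    control = lme4::lmerControl(
                                      check.conv.singular = "ignore",
                                      calc.derivs = FALSE)))
      })
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    beta <- fe[["met"]]
    se_b <- se[[which(names(fe) == "met")]]
  } else {
    mm <- stats::model.matrix(stats::as.formula(paste0("~ ", rhs)), data = dat)
    fit <- gee_exchangeable(dat$y, mm, dat$pair_id)
    converged <- fit$converged
    k <- which(colnames(mm) == "met")
    beta <- fit$coefficients[[k]]
    se_b <- fit$se[[k]]
  }
  p <- 2 * stats::pnorm(-abs(beta / se_b))
  data.frame(metabolite = metabolite_name, lipid = lipid,
             beta = beta, se = se_b, p_value = p, n = nrow(dat),
             model = if (adjust_bmi) "bmi_adjusted" else "main",
             engine = engine, converged = converged,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Metabolome-wide association screen against the lipid panel
#'
#' Fits [fit_association()] for every metabolite column of `met_z` against
#' each lipid and applies Benjamini-Hochberg FDR control within each lipid
#' family (all metabolites tested against that lipid).
#'
#' @param cohort Transformed cohort data.frame.
#' @param met_z Standardized metabolite matrix (individuals x metabolites),
#'   rownames matching `cohort$individual_id`.
#' @param lipids Lipid columns to screen (default all four).
#' @param fdr_threshold Significance call threshold on the q-value
#'   (default 0.05).
#' @inheritParams fit_association
#' @return data.frame of association records with `q_value` and `significant`.
#' @export
associate <- function(cohort, met_z, lipids = .LIPIDS, adjust_bmi = FALSE,
                      engine = c("lmm", "gee"), reml = TRUE,
                      fdr_threshold = 0.05) {
  engine <- match.arg(engine)
  stopifnot(is.matrix(met_z), !is.null(rownames(met_z)))
  idx <- match(cohort$individual_id, rownames(met_z))
  if (anyNA(idx))
    stop("cohort individuals missing from the metabolite matrix")
  met_z <- met_z[idx, , drop = FALSE]
  lipids <- intersect(lipids, names(cohort))
  recs <- vector("list", ncol(met_z) * length(lipids))
  k <- 0L
  for (lip in lipids) {
    for (j in seq_len(ncol(met_z))) {
      k <- k + 1L
      recs[[k]] <- fit_association(cohort, met_z[, j], lip,
                                   adjust_bmi = adjust_bmi, engine = engine,
                                   reml = reml,
                                   metabolite_name = colnames(met_z)[j])
    }
  }
  out <- do.call(rbind, recs)
  adjust_fdr(out, family = "lipid", threshold = fdr_threshold)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values. Given a numeric vector of P values, returns the
#' q-values. Given a data.frame of association records, appends `q_value` and
#' `significant`, computed within each `family` group (by default per lipid,
#' i.e. one family = all metabolites tested against one lipid); records
#' flagged as non-converged are excluded from the family and get `NA`.
#'
#' @param records Numeric P-value vector or association record data.frame.
#' @param family Grouping column for data.frame input (default `"lipid"`).
#' @param threshold Significance call at `q < threshold` (default 0.05).
#' @return q-value vector, or the records with `q_value`/`significant` added.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjust_fdr <- function(records, family = "lipid", threshold = 0.05) {
  if (is.numeric(records)) {
    if (length(records) == 0L) stop("empty P-value family")
    return(stats::p.adjust(records, method = "BH"))
  }
  stopifnot(is.data.frame(records), "p_value" %in% names(records))
  if (nrow(records) == 0L) stop("empty record set")
  ok <- if ("converged" %in% names(records)) records$converged else
    rep(TRUE, nrow(records))
  records$q_value <- NA_real_
  groups <- if (family %in% names(records)) records[[family]] else
    rep("all", nrow(records))
  for (g in unique(groups)) {
    sel <- groups == g & ok
    if (any(sel))
      records$q_value[sel] <- stats::p.adjust(records$p_value[sel],
                                              method = "BH")
  }
  records$significant <- !is.na(records$q_value) & records$q_value < threshold
  records
}

#' Overweight-stratified association with interaction test
#'
#' Fits the metabolite-lipid association separately in the lean
#' (`BMI < cutoff`) and overweight (`BMI >= cutoff`) strata, and tests
#' effect-measure modification with a 1-df likelihood ratio test comparing
#' pooled ML mixed-model fits with and without the metabolite-by-overweight
#' interaction term (ML, not REML, since REML likelihoods are not comparable
#' across fixed-effect structures).
#'
#' @inheritParams fit_association
#' @param bmi_cutoff Overweight threshold in kg/m^2 (default 24; a BMI of
#'   exactly 24 is overweight).
#' @return data.frame with one record per stratum (`model` =
#'   `stratum_lean` / `stratum_overweight`) carrying the shared
#'   `interaction_p`; a stratum below `min_n` is flagged (`NA` estimates) and
#'   the interaction test is skipped.
#' @export
stratified_interaction <- function(cohort, metabolite, lipid,
                                   bmi_cutoff = 24, min_n = 10L,
                                   metabolite_name = NULL) {
  stopifnot("BMI" %in% names(cohort))
  if (is.character(metabolite) && length(metabolite) == 1L) {
    metabolite_name <- metabolite_name %||% metabolite
    met <- cohort[[metabolite]]
  } else {
    metabolite_name <- metabolite_name %||% "metabolite"
    met <- as.numeric(metabolite)
  }
  ow <- cohort$BMI >= bmi_cutoff
  strata <- list(stratum_lean = which(!is.na(ow) & !ow),
                 stratum_overweight = which(!is.na(ow) & ow))
  recs <- list(); skip <- FALSE
  for (nm in names(strata)) {
    rows <- strata[[nm]]
    rec <- tryCatch(
      fit_association(cohort[rows, , drop = FALSE], met[rows], lipid,
                      min_n = min_n, metabolite_name = metabolite_name),
      error = function(e) {
        skip <<- TRUE
        data.frame(metabolite = metabolite_name, lipid = lipid,
                   beta = NA_real_, se = NA_real_, p_value = NA_real_,
                   n = length(rows), model = nm, engine = "lmm",
                   converged = FALSE, stringsAsFactors = FALSE)
      })
    rec$model <- nm
    recs[[nm]] <- rec
  }
  out <- do.call(rbind, recs)
  out$interaction_p <- NA_real_
  if (!skip) {
    covs <- intersect(.COVARIATES, names(cohort))
    dat <- data.frame(y = cohort[[lipid]], met = met, ow = ow,
                      pair_id = cohort$pair_id,
                      cohort[, covs, drop = FALSE])
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    covs <- covs[vapply(covs, function(cv) length(unique(dat[[cv]])) > 1L,
                        logical(1))]
    rhs <- paste(c("met", "ow", covs), collapse = " + ")
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                              calc.derivs = FALSE)
    m0 <- suppressWarnings(lme4::lmer(
      stats::as.formula(paste0("y ~ ", rhs, " + (1 | pair_id)")),
      data = dat, REML = FALSE, control = ctrl))
    m1 <- suppressWarnings(lme4::lmer(
      stats::as.formula(paste0("y ~ ", rhs, " + met:ow + (1 | pair_id)")),
      data = dat, REML = FALSE, control = ctrl))
    lr <- 2 * (as.numeric(stats::logLik(m1)) - as.numeric(stats::logLik(m0)))
    out$interaction_p <- stats::pchisq(max(lr, 0), df = 1L, lower.tail = FALSE)
  }
  rownames(out) <- NULL
  out
}
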