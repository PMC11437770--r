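#' Build the co-twin regression design
#'
#' Arranges complete MZ pairs for co-twin regression: each member of each pair
#' contributes one row as "self", carrying their own outcome (`y_self`), their
#' own predictor (`x_self`) and their co-twin's predictor (`x_cotwin`). Pairs
#' with a missing predictor or outcome in either member are dropped entirely
#' (both roles need both members' values); singletons never enter.
#'
#' @param cohort Cohort data.frame with `pair_id` and the two trait columns.
#' @param x_name Predictor column name.
#' @param y_name Outcome column name.
#' @param min_pairs Minimum number of usable pairs (default 30).
#' @return A data.frame of class `cotwin_design` with columns `pair_id`,
#'   `individual_id` (if present), `y_self`, `x_self`, `x_cotwin`; attribute
#'   `n_pairs`.
#' @export
build_cotwin_design <- function(cohort, x_name, y_name, min_pairs = 30L) {
  stopifnot(is.data.frame(cohort), x_name %in% names(cohort),
            y_name %in% names(cohort), "pair_id" %in% names(cohort))
  idx <- split(seq_len(nrow(cohort)), cohort$pair_id)
  idx <- idx[lengths(idx) == 2L]
  usable <- vapply(idx, function(ii) {
    all(!is.na(cohort[[x_name]][ii])) && all(!is.na(cohort[[y_name]][ii]))
  }, logical(1))
  idx <- idx[usable]
  if (length(idx) < min_pairs)
    stop(sprintf("only %d usable complete pairs (need >= %d) for %s vs %s",
                 length(idx), min_pairs, x_name, y_name))
  i1 <- vapply(idx, `[`, integer(1), 1L)
  i2 <- vapply(idx, `[`, integer(1), 2L)
  design <- data.frame(
    pair_id = rep(cohort$pair_id[i1], each = 2L),
    y_self = as.vector(rbind(cohort[[y_name]][i1], cohort[[y_name]][i2])),
    x_self = as.vector(rbind(cohort[[x_name]][i1], cohort[[x_name]][i2])),
    x_cotwin = as.vector(rbind(cohort[[x_name]][i2], cohort[[x_name]][i1])),
    stringsAsFactors = FALSE)
  if ("individual_id" %in% names(cohort))
    design$individual_id <- as.vector(rbind(cohort$individual_id[i1],
                                            cohort$individual_id[i2]))
  attr(design, "n_pairs") <- length(idx)
  attr(design, "x_name") <- x_name
  attr(design, "y_name") <- y_name
  class(design) <- c("cotwin_design", "data.frame")
  design
}

# Per-pair arrays (member 1 outcome/predictor, member 2 outcome/predictor)
# for the lean bootstrap path.
.design_arrays <- function(design) {
  odd <- seq(1L, nrow(design), by = 2L)
  list(y1 = design$y_self[odd], y2 = design$y_self[odd + 1L],
       x1 = design$x_self[odd], x2 = design$x_self[odd + 1L])
}

#' Fit the three ICE FALCON co-twin regression models
#'
#' Model 1 regresses the outcome on the subject's own predictor
#' (`E(Y_self) = a + b_self X_self`), Model 2 on the co-twin's predictor
#' (`E(Y_self) = a + b_cotwin X_cotwin`), and Model 3 on both
#' (`E(Y_self) = a + b'_self X_self + b'_cotwin X_cotwin`). All three are
#' marginal linear fits with an exchangeable working correlation within pairs
#' and cluster-robust sandwich standard errors. Coefficient changes are the
#' Model-3 estimates minus their marginal counterparts.
#'
#' @param design A [build_cotwin_design()] result.
#' @param rho Fixed working correlation, or `NULL` (default) to estimate it.
#' @return A list of class `falcon_triplet`: `coefs` (data.frame with rows
#'   `beta_self`, `beta_cotwin`, `bprime_self`, `bprime_cotwin`; columns
#'   `estimate`, `se`, `p`), `change_self`, `change_cotwin`, `rho`
#'   (per model), `n_pairs`.
#' @export
fit_three_models <- function(design, rho = NULL) {
  stopifnot(inherits(design, "cotwin_design"))
  if (stats::sd(design$x_self) == 0)
    stop("predictor is constant; co-twin regression design is singular")
  id <- design$pair_id
  m1 <- gee_exchangeable(design$y_self, cbind(1, x = design$x_self), id, rho = rho)
  m2 <- gee_exchangeable(design$y_self, cbind(1, x = design$x_cotwin), id, rho = rho)
  m3 <- gee_exchangeable(design$y_self,
                         cbind(1, xs = design$x_self, xc = design$x_cotwin),
                         id, rho = rho)
  coefs <- data.frame(
    term = c("beta_self", "beta_cotwin", "bprime_self", "bprime_cotwin"),
    model = c(1L, 2L, 3L, 3L),
    estimate = c(m1$coefficients[2L], m2$coefficients[2L],
                 m3$coefficients[2L], m3$coefficients[3L]),
    se = c(m1$se[2L], m2$se[2L], m3$se[2L], m3$se[3L]),
    p = c(m1$p[2L], m2$p[2L], m3$p[2L], m3$p[3L]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefs = coefs,
                 change_self = coefficient_change(coefs$estimate[1L],
                                                  coefs$estimate[3L]),
                 change_cotwin = coefficient_change(coefs$estimate[2L],
                                                    coefs$estimate[4L]),
                 rho = c(m1 = m1$rho, m2 = m2$rho, m3 = m3$rho),
                 converged = m1$converged && m2$converged && m3$converged,
                 n_pairs = attr(design, "n_pairs")),
            class = "falcon_triplet")
}

#' Change between a marginal and a conditional coefficient
#'
#' The ICE FALCON change statistic: the Model-3 (conditional) coefficient
#' minus its Model-1 or Model-2 (marginal) counterpart.
#'
#' @param marginal Marginal coefficient (Model 1 or 2).
#' @param conditional Conditional coefficient (Model 3).
#' @return `conditional - marginal`.
#' @examples
#' coefficient_change(0.0546, 0.1230)  # 0.0684
#' @export
coefficient_change <- function(marginal, conditional) {
  stopifnot(is.finite(marginal), is.finite(conditional))
  conditional - marginal
}

# One-sided P for a coefficient change given its bootstrap SE.
# "attenuation": H1 is a change toward the null relative to the marginal
# coefficient; P = P(Z >= |z|) when the observed change points that way,
# else 1 - that value (equivalently pnorm(sign(marginal) * z)).
# "observed": one-sided in the direction of the observed change.
.change_p <- function(delta, se, marginal,
                      alternative = c("attenuation", "observed", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.finite(se) || se <= 0) return(NA_real_)
  z <- delta / se
  switch(alternative,
         attenuation = stats::pnorm(sign(marginal) * z),
         observed = stats::pnorm(-abs(z)),
         two.sided = 2 * stats::pnorm(-abs(z)))
}

#' Pair-resampling bootstrap for ICE FALCON coefficient changes
#'
#' Resamples twin pairs with replacement (both members move together), each
#' resample having the same number of pairs as the original design; refits the
#' three co-twin regression models on every resample and records both
#' coefficient changes. The bootstrap SE is the sample SD of the `B` change
#' estimates; one-sided P values are computed from the observed change and the
#' bootstrap SE on the normal scale. Resamples whose fit fails (for example a
#' resample with a constant predictor) are redrawn and counted; more than 5%
#' failures aborts.
#'
#' @param design A [build_cotwin_design()] result.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param triplet The point-estimate [fit_three_models()] fit (refitted if
#'   missing); supplies the observed changes and marginal signs.
#' @param rho Fixed working correlation, or `NULL` to estimate per resample.
#' @param alternative Direction convention for the one-sided change P:
#'   `"attenuation"` (default; the hypothesis of a change toward the null),
#'   `"observed"` (direction of the observed change, the convention used for
#'   printed change P values), or `"two.sided"`.
#' @return A list of class `falcon_boot`: `se_change_self`,
#'   `se_change_cotwin`, `p_change_self`, `p_change_cotwin`,
#'   `p_change_self_observed`, `p_change_cotwin_observed`, `B`, `n_failed`,
#'   `degenerate` (TRUE when a bootstrap SE is zero).
#' @export
bootstrap_changes <- function(design, B = 1000L, seed = 1L,
                              triplet = fit_three_models(design, rho = rho),
                              rho = NULL,
                              alternative = c("attenuation", "observed",
                                              "two.sided")) {
  stopifnot(inherits(design, "cotwin_design"), B >= 2L)
  alternative <- match.arg(alternative)
  arr <- .design_arrays(design)
  P <- length(arr$y1)
  set.seed(seed)
  d_self <- numeric(B); d_cotwin <- numeric(B)
  n_failed <- 0L
  max_failed <- ceiling(0.05 * B)
  b <- 1L
  while (b <= B) {
    ii <- sample.int(P, P, replace = TRUE)
    res <- tryCatch({
      y1 <- arr$y1[ii]; y2 <- arr$y2[ii]
      x1 <- arr$x1[ii]; x2 <- arr$x2[ii]
      c1 <- .falcon_coefs(y1, y2, x1, x2, 1L, rho_fixed = rho)
      c2 <- .falcon_coefs(y1, y2, x1, x2, 2L, rho_fixed = rho)
      c3 <- .falcon_coefs(y1, y2, x1, x2, 3L, rho_fixed = rho)
      c(c3[2L] - c1[2L], c3[3L] - c2[2L])
    }, error = function(e) NULL)
    if (is.null(res) || any(!is.finite(res))) {
      n_failed <- n_failed + 1L
      if (n_failed > max_failed)
        stop(sprintf("more than 5%% of bootstrap resamples failed (%d of %d)",
                     n_failed, B))
      next
    }
    d_self[b] <- res[1L]; d_cotwin[b] <- res[2L]
    b <- b + 1L
  }
  se_self <- stats::sd(d_self)
  se_cotwin <- stats::sd(d_cotwin)
  est <- triplet$coefs$estimate
  out <- list(
    se_change_self = se_self,
    se_change_cotwin = se_cotwin,
    p_change_self = .change_p(triplet$change_self, se_self, est[1L],
                              alternative),
    p_change_cotwin = .change_p(triplet$change_cotwin, se_cotwin, est[2L],
                                alternative),
    p_change_self_observed = .change_p(triplet$change_self, se_self, est[1L],
                                       "observed"),
    p_change_cotwin_observed = .change_p(triplet$change_cotwin, se_cotwin,
                                         est[2L], "observed"),
    B = as.integer(B), n_failed = n_failed,
    degenerate = (se_self == 0 || se_cotwin == 0),
    alternative = alternative, seed = as.integer(seed))
  class(out) <- "falcon_boot"
  out
}

# Residualize a variable on the shared covariates (complete cases), then
# z-score. Non-varying covariates are dropped from the adjustment.
.residualize <- function(v, cohort, covariates) {
  covs <- intersect(covariates, names(cohort))
  covs <- covs[vapply(covs, function(cv) {
    length(unique(cohort[[cv]][!is.na(cohort[[cv]])])) > 1L
  }, logical(1))]
  if (length(covs) > 0L) {
    dat <- cohort[, covs, drop = FALSE]
    dat$.v <- v
    fit <- stats::lm(.v ~ ., data = dat, na.action = stats::na.exclude)
    v <- stats::residuals(fit)
  }
  as.numeric(scale(v))
}

#' Bidirectional ICE FALCON analysis
#'
#' Runs the full ICE FALCON procedure for a trait pair: the three co-twin
#' regression models with `x_name` as predictor and `y_name` as outcome, the
#' same with the roles reversed, pair-bootstrap SEs and one-sided P values for
#' the coefficient changes in both directions, and the evidence-pattern
#' classification of [classify_pattern()].
#'
#' By default both traits are residualized on the pair-shared covariates
#' (age, gender, region, survey year) and z-scored before the co-twin design
#' is built; because MZ co-twins share these covariates they cannot confound
#' the within-pair contrasts, but they do affect the marginal Model-1 and
#' Model-2 coefficients.
#'
#' @param cohort Cohort data.frame containing `pair_id`, the two trait columns
#'   and (if `residualize`) the covariates.
#' @param x_name,y_name Trait columns; `x_name` is the candidate cause in the
#'   `X -> Y` labelling of the classification.
#' @param B Bootstrap resamples per direction (default 1000).
#' @param seed Master seed; direction sub-seeds are derived from the predictor
#'   name so that swapping `x_name` and `y_name` exactly exchanges the two
#'   directions.
#' @param alpha Significance level for the classification (default 0.05).
#' @param residualize Adjust both traits for shared covariates first
#'   (default TRUE).
#' @param covariates Covariates used when `residualize = TRUE`.
#' @param rho Fixed working correlation, or `NULL` (default) to estimate it.
#' @param min_pairs Minimum usable pairs per direction.
#' @return A list of class `falcon_result` with elements `x_name`, `y_name`,
#'   `directions` (two lists, `x_as_predictor` and `y_as_predictor`, each with
#'   `triplet` and `boot`), `classification`, `alpha`, `B`, `seed`, `n_pairs`.
#' @export
ice_falcon <- function(cohort, x_name, y_name, B = 1000L, seed = 1L,
                       alpha = 0.05, residualize = TRUE,
                       covariates = c("age", "gender", "region", "survey_year"),
                       rho = NULL, min_pairs = 30L) {
  stopifnot(is.data.frame(cohort))
  work <- cohort
  if (residualize) {
    work[[x_name]] <- .residualize(cohort[[x_name]], cohort, covariates)
    work[[y_name]] <- .residualize(cohort[[y_name]], cohort, covariates)
  } else {
    work[[x_name]] <- as.numeric(scale(cohort[[x_name]]))
    work[[y_name]] <- as.numeric(scale(cohort[[y_name]]))
  }
  run_dir <- function(pred, outc) {
    design <- build_cotwin_design(work, pred, outc, min_pairs = min_pairs)
    triplet <- fit_three_models(design, rho = rho)
    boot <- bootstrap_changes(design, B = B,
                              seed = .substream(seed, 7L + sum(utf8ToInt(pred))),
                              triplet = triplet, rho = rho)
    list(triplet = triplet, boot = boot)
  }
  dir_x <- run_dir(x_name, y_name)
  dir_y <- run_dir(y_name, x_name)
  res <- structure(list(x_name = x_name, y_name = y_name,
                        directions = list(x_as_predictor = dir_x,
                                          y_as_predictor = dir_y),
                        alpha = alpha, B = as.integer(B),
                        seed = as.integer(seed),
                        n_pairs = dir_x$triplet$n_pairs),
                   class = "falcon_result")
  res$classification <- classify_pattern(res, alpha = alpha)
  res
}

#' Classify the ICE FALCON evidence pattern
#'
#' Deterministic rule set mapping the fitted coefficients and P values of a
#' bidirectional ICE FALCON run to one of five labels. The causal template is
#' evaluated in the direction where the candidate cause is the predictor:
#' a significant own-predictor coefficient (Model 1), no significant change in
#' it after conditioning on the co-twin's predictor, a significant attenuation
#' of the co-twin coefficient toward the null (one-sided bootstrap P), and a
#' Model-3 co-twin coefficient that has attenuated to become null (robust P
#' at or above `alpha`). Familial confounding requires a significant marginal
#' co-twin coefficient with significant attenuation of both Model-3
#' coefficients in at least one direction. Both causal templates met gives
#' `bidirectional_or_mixed`; nothing met gives `inconclusive`.
#'
#' @param result A `falcon_result` from [ice_falcon()].
#' @param alpha Significance level (default 0.05).
#' @return One of `"consistent_causal_X_to_Y"`, `"consistent_causal_Y_to_X"`,
#'   `"consistent_familial_confounding"`, `"bidirectional_or_mixed"`,
#'   `"inconclusive"`.
#' @export
classify_pattern <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "falcon_result"))
  tmpl <- function(d) {
    cf <- d$triplet$coefs
    p_self_m1 <- cf$p[1L]; p_bprime_cotwin <- cf$p[4L]
    ok <- p_self_m1 < alpha &&
      !is.na(d$boot$p_change_self) && d$boot$p_change_self >= alpha &&
      !is.na(d$boot$p_change_cotwin) && d$boot$p_change_cotwin < alpha &&
      p_bprime_cotwin >= alpha
    isTRUE(ok)
  }
  fam <- function(d) {
    cf <- d$triplet$coefs
    isTRUE(cf$p[2L] < alpha &&
             !is.na(d$boot$p_change_self) && d$boot$p_change_self < alpha &&
             !is.na(d$boot$p_change_cotwin) && d$boot$p_change_cotwin < alpha)
  }
  dx <- result$directions$x_as_predictor
  dy <- result$directions$y_as_predictor
  causal_xy <- tmpl(dx)   # X predictor, Y outcome: X -> Y
  causal_yx <- tmpl(dy)
  if (causal_xy && causal_yx) return("bidirectional_or_mixed")
  if (causal_xy) return("consistent_causal_X_to_Y")
  if (causal_yx) return("consistent_causal_Y_to_X")
  if (fam(dx) || fam(dy)) return("consistent_familial_confounding")
  "inconclusive"
}

#' @export
print.falcon_result <- function(x, ...) {
  cat(sprintf("ICE FALCON: %s vs %s (%d pairs, B = %d)\n",
              x$x_name, x$y_name, x$n_pairs, x$B))
  cat(sprintf("Classification: %s (alpha = %g)\n\n", x$classification,
              x$alpha))
  for (nm in names(x$directions)) {
    d <- x$directions[[nm]]
    pred <- if (nm == "x_as_predictor") x$x_name else x$y_name
    outc <- if (nm == "x_as_predictor") x$y_name else x$x_name
    cat(sprintf("-- predictor %s, outcome %s --\n", pred, outc))
    print(d$triplet$coefs, digits = 4)
    cat(sprintf("change_self  = %+.4f (boot SE %.4f, one-sided P %.3g)\n",
                d$triplet$change_self, d$boot$se_change_self,
                d$boot$p_change_self))
    cat(sprintf("change_cotwin= %+.4f (boot SE %.4f, one-sided P %.3g)\n\n",
                d$triplet$change_cotwin, d$boot$se_change_cotwin,
                d$boot$p_change_cotwin))
  }
  invisible(x)
}

#' Flatten a bidirectional ICE FALCON result to one table row per direction
#'
#' Column layout mirrors the Model 1 / Model 2 / Model 3 / Change structure of
#' co-twin regression result tables.
#'
#' @param x A `falcon_result`.
#' @param ... Unused.
#' @return A two-row data.frame (one per direction).
#' @export
as.data.frame.falcon_result <- function(x, ...) {
  row_for <- function(nm) {
    d <- x$directions[[nm]]
    cf <- d$triplet$coefs
    data.frame(
      x_name = x$x_name, y_name = x$y_name,
      predictor = if (nm == "x_as_predictor") x$x_name else x$y_name,
      outcome = if (nm == "x_as_predictor") x$y_name else x$x_name,
      n_pairs = d$triplet$n_pairs,
      beta_self = cf$estimate[1L], se_self = cf$se[1L], p_self = cf$p[1L],
      beta_cotwin = cf$estimate[2L], se_cotwin = cf$se[2L],
      p_cotwin = cf$p[2L],
      bprime_self = cf$estimate[3L], se_bprime_self = cf$se[3L],
      p_bprime_self = cf$p[3L],
      bprime_cotwin = cf$estimate[4L], se_bprime_cotwin = cf$se[4L],
      p_bprime_cotwin = cf$p[4L],
      change_self = d$triplet$change_self,
      boot_se_change_self = d$boot$se_change_self,
      p_change_self = d$boot$p_change_self,
      change_cotwin = d$triplet$change_cotwin,
      boot_se_change_cotwin = d$boot$se_change_cotwin,
      p_change_cotwin = d$boot$p_change_cotwin,
      B = d$boot$B, classification = x$classification,
      stringsAsFactors = FALSE)
  }
  rbind(row_for("x_as_predictor"), row_for("y_as_predictor"))
}
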