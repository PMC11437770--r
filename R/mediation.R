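#' Pearson prescreen of metabolite-trait pairs
#'
#' Computes the pairwise Pearson correlation and two-sided P value for every
#' metabolite-by-trait combination and keeps pairs with `P < p_threshold`
#' (the eligibility screen applied before mediation analysis). Constant
#' columns are skipped with a log entry in the `skipped` attribute.
#'
#' @param met_z Standardized metabolite matrix (individuals x metabolites).
#' @param traits data.frame or matrix of numeric trait columns, rows aligned
#'   with `met_z`.
#' @param p_threshold Eligibility threshold (default 0.05).
#' @return data.frame with `metabolite`, `trait`, `r`, `p_value`, `eligible`;
#'   attribute `skipped` lists constant columns.
#' @export
prescreen_pearson <- function(met_z, traits, p_threshold = 0.05) {
  met_z <- as.matrix(met_z)
  traits <- as.data.frame(traits)
  stopifnot(nrow(met_z) == nrow(traits))
  is_const <- function(v) {
    v <- v[!is.na(v)]
    length(v) < 3L || stats::sd(v) == 0
  }
  skipped <- c(colnames(met_z)[apply(met_z, 2L, is_const)],
               names(traits)[vapply(traits, is_const, logical(1))])
  mets <- setdiff(colnames(met_z), skipped)
  trs <- setdiff(names(traits), skipped)
  out <- expand.grid(metabolite = mets, trait = trs, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  stat <- t(mapply(function(m, tr) {
    ct <- stats::cor.test(met_z[, m], traits[[tr]])
    c(ct$estimate, ct$p.value)
  }, out$metabolite, out$trait))
  out$r <- stat[, 1L]
  out$p_value <- stat[, 2L]
  out$eligible <- out$p_value < p_threshold
  attr(out, "skipped") <- skipped
  out
}

#' Causal mediation analysis by quasi-Bayesian Monte Carlo
#'
#' Fits the two linear models `mediator ~ exposure + covariates` and
#' `outcome ~ exposure + mediator + covariates`, draws `n_sims` coefficient
#' vectors from their joint asymptotic normal distribution, and forms per-draw
#' effects: the average causal mediation effect (ACME, product of the
#' exposure-to-mediator and mediator-to-outcome paths), the average direct
#' effect (ADE), and the total effect (their sum, a draw-wise identity for the
#' linear no-interaction model). P values are two-sided Monte-Carlo tail
#' probabilities (doubled, floored at `2 / n_sims`); confidence intervals are
#' percentile intervals of the draws.
#'
#' @param data data.frame with the three variables and covariates.
#' @param exposure,mediator,outcome Column names.
#' @param covariates Covariate columns to adjust both models for (default
#'   age, gender, region, survey year; those absent or constant are dropped).
#' @param n_sims Monte-Carlo draws (default 1000).
#' @param seed Integer seed.
#' @param min_n Minimum complete cases (default 30).
#' @return A list of class `mediation_record`: `acme`, `ade`, `total`
#'   (each a list with `estimate`, `ci`, `p`), `prop_mediated`,
#'   `prop_mediated_flagged` (TRUE when ACME and total disagree in sign),
#'   `draws`, `n`, `n_sims`, `seed`, and the variable names.
#' @export
fit_mediation <- function(data, exposure, mediator, outcome,
                          covariates = c("age", "gender", "region",
                                         "survey_year"),
                          n_sims = 1000L, seed = 1L, min_n = 30L) {
  stopifnot(all(c(exposure, mediator, outcome) %in% names(data)),
            n_sims >= 2L)
  covs <- intersect(covariates, names(data))
  dat <- data[, c(exposure, mediator, outcome, covs), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < min_n)
    stop(sprintf("only %d complete cases (need >= %d) for %s -> %s -> %s",
                 nrow(dat), min_n, exposure, mediator, outcome))
  covs <- covs[vapply(covs, function(cv) length(unique(dat[[cv]])) > 1L,
                      logical(1))]
  r_em <- stats::cor(dat[[exposure]], dat[[mediator]])
  if (abs(r_em) > 0.99)
    stop(sprintf("exposure and mediator are collinear (|r| = %.3f)",
                 abs(r_em)))
  rhs_m <- paste(c(exposure, covs), collapse = " + ")
  rhs_o <- paste(c(exposure, mediator, covs), collapse = " + ")
  bq <- function(nm) paste0("`", nm, "`")
  m_med <- stats::lm(stats::as.formula(paste(bq(mediator), "~", rhs_m)),
                     data = dat)
  m_out <- stats::lm(stats::as.formula(paste(bq(outcome), "~", rhs_o)),
                     data = dat)
  set.seed(seed)
  draw_med <- MASS::mvrnorm(n_sims, stats::coef(m_med), stats::vcov(m_med))
  draw_out <- MASS::mvrnorm(n_sims, stats::coef(m_out), stats::vcov(m_out))
  a <- draw_med[, exposure]
  b <- draw_out[, mediator]
  cp <- draw_out[, exposure]
  acme <- a * b
  ade <- cp
  total <- acme + ade
  mc_p <- function(d) max(2 * min(mean(d <= 0), mean(d >= 0)), 2 / n_sims)
  summ <- function(d) list(estimate = mean(d),
                           ci = stats::quantile(d, c(0.025, 0.975),
                                                names = FALSE),
                           p = mc_p(d))
  acme_s <- summ(acme); ade_s <- summ(ade); total_s <- summ(total)
  prop <- acme_s$estimate / total_s$estimate
  structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                 acme = acme_s, ade = ade_s, total = total_s,
                 prop_mediated = prop,
                 prop_mediated_flagged =
                   sign(acme_s$estimate) != sign(total_s$estimate),
                 draws = data.frame(acme = acme, ade = ade, total = total),
                 n = nrow(dat), n_sims = as.integer(n_sims),
                 seed = as.integer(seed)),
            class = "mediation_record")
}

#' @export
print.mediation_record <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s (n = %d, %d draws)\n",
              x$exposure, x$mediator, x$outcome, x$n, x$n_sims))
  for (nm in c("acme", "ade", "total")) {
    e <- x[[nm]]
    cat(sprintf("  %-5s %+0.4f [%+0.4f, %+0.4f]  P = %.3g\n",
                toupper(nm), e$estimate, e$ci[1], e$ci[2], e$p))
  }
  cat(sprintf("  proportion mediated: %.1f%%%s\n", 100 * x$prop_mediated,
              if (x$prop_mediated_flagged) " (flagged: sign mismatch)" else ""))
  invisible(x)
}

#' Bidirectional mediation with the asymmetric linkage rule
#'
#' Fits both candidate orderings for an exposure and two downstream variables:
#' the forward ordering `exposure -> mediator -> outcome` and the inverse
#' ordering with the mediator and outcome roles exchanged. A mediation
#' linkage is declared for the forward ordering only when its mediation P is
#' below `alpha` while the inverse ordering's is not (`p_mediation < alpha`
#' and `p_inverse > alpha`); both orderings significant gives no linkage.
#'
#' @inheritParams fit_mediation
#' @param alpha Linkage threshold (default 0.05).
#' @return A list of class `mediation_pair`: `forward`, `inverse`
#'   (two `mediation_record`s), `p_mediation`, `p_inverse`, `verdict`
#'   (`"linkage"` / `"no_linkage"`), `prop_mediated_pct` (rounded integer
#'   percentage for the forward ordering).
#' @export
bidirectional_mediation <- function(data, exposure, mediator, outcome,
                                    covariates = c("age", "gender", "region",
                                                   "survey_year"),
                                    n_sims = 1000L, seed = 1L, alpha = 0.05,
                                    min_n = 30L) {
  fwd <- fit_mediation(data, exposure, mediator, outcome,
                       covariates = covariates, n_sims = n_sims,
                       seed = .substream(seed, 11L), min_n = min_n)
  inv <- fit_mediation(data, exposure, outcome, mediator,
                       covariates = covariates, n_sims = n_sims,
                       seed = .substream(seed, 12L), min_n = min_n)
  p_f <- fwd$acme$p; p_i <- inv$acme$p
  structure(list(forward = fwd, inverse = inv,
                 p_mediation = p_f, p_inverse = p_i,
                 verdict = if (p_f < alpha && p_i > alpha) "linkage" else
                   "no_linkage",
                 prop_mediated_pct = round(100 * fwd$prop_mediated),
                 alpha = alpha),
            class = "mediation_pair")
}

#' @export
print.mediation_pair <- function(x, ...) {
  cat(sprintf("Bidirectional mediation: %s -> %s -> %s\n",
              x$forward$exposure, x$forward$mediator, x$forward$outcome))
  cat(sprintf("  P_mediation = %.3g, P_inverse = %.3g -> %s",
              x$p_mediation, x$p_inverse, x$verdict))
  if (x$verdict == "linkage")
    cat(sprintf(" (%d%% mediated)", x$prop_mediated_pct))
  cat("\n")
  invisible(x)
}

#' Flatten mediation results to one row per ordering
#'
#' @param x A `mediation_pair`.
#' @param ... Unused.
#' @return Two-row data.frame (forward and inverse orderings).
#' @export
as.data.frame.mediation_pair <- function(x, ...) {
  row_for <- function(rec, ordering) {
    data.frame(ordering = ordering, exposure = rec$exposure,
               mediator = rec$mediator, outcome = rec$outcome,
               acme = rec$acme$estimate, acme_lo = rec$acme$ci[1],
               acme_hi = rec$acme$ci[2], acme_p = rec$acme$p,
               ade = rec$ade$estimate, total = rec$total$estimate,
               total_p = rec$total$p,
               prop_mediated = rec$prop_mediated,
               n = rec$n, n_sims = rec$n_sims,
               verdict = x$verdict, stringsAsFactors = FALSE)
  }
  rbind(row_for(x$forward, "forward"), row_for(x$inverse, "inverse"))
}
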