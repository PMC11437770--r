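#' Per-metabolite analytical coefficient of variation in QC samples
#'
#' CV is the sample SD divided by the mean of the QC-replicate measurements,
#' on the raw concentration scale. Metabolites with fewer than two detected QC
#' values, or a non-positive mean, have an undefined CV (`NA`).
#'
#' @param qc A QC matrix (injections x metabolites, `NA` = not detected) or a
#'   `metabolite_matrix`.
#' @return Named numeric vector of CVs (`NA` where undefined).
#' @examples
#' compute_cv(cbind(a = c(1, 2, 3)))  # sample SD 1 / mean 2 = 0.5
#' @export
compute_cv <- function(qc) {
  if (inherits(qc, "metabolite_matrix")) qc <- qc$qc
  stopifnot(is.matrix(qc))
  apply(qc, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    m <- mean(v)
    if (m <= 0) return(NA_real_)
    stats::sd(v) / m
  })
}

#' Quality-control report for a metabolite panel
#'
#' Computes, per metabolite, the analytical CV and the occurrence (fraction of
#' QC injections with a detected value) and assigns a filter verdict:
#' `excluded_cv` when CV is above `cv_threshold` (strictly) or undefined,
#' `excluded_occurrence` when occurrence is below `occurrence_threshold`
#' (strictly), else `kept`. Thresholds are strict, so a CV of exactly 0.30 or
#' an occurrence of exactly 0.50 is kept.
#'
#' @param mm A `metabolite_matrix` (or a QC matrix).
#' @param cv_threshold CV exclusion threshold (default 0.30).
#' @param occurrence_threshold Occurrence exclusion threshold (default 0.50).
#' @return A data.frame of class `qc_report` with columns `metabolite`, `cv`,
#'   `occurrence`, `verdict`, and attributes `counts` (kept/excluded tallies)
#'   and the thresholds used.
#' @export
qc_report <- function(mm, cv_threshold = 0.30, occurrence_threshold = 0.50) {
  qc <- if (inherits(mm, "metabolite_matrix")) mm$qc else mm
  stopifnot(is.matrix(qc))
  cv <- compute_cv(qc)
  occurrence <- colMeans(!is.na(qc))
  verdict <- ifelse(is.na(cv) | cv > cv_threshold, "excluded_cv",
                    ifelse(occurrence < occurrence_threshold,
                           "excluded_occurrence", "kept"))
  rep_df <- data.frame(metabolite = colnames(qc), cv = cv,
                       occurrence = occurrence, verdict = verdict,
                       row.names = NULL, stringsAsFactors = FALSE)
  attr(rep_df, "counts") <- table(factor(
    verdict, levels = c("kept", "excluded_cv", "excluded_occurrence")))
  attr(rep_df, "cv_threshold") <- cv_threshold
  attr(rep_df, "occurrence_threshold") <- occurrence_threshold
  class(rep_df) <- c("qc_report", "data.frame")
  rep_df
}

#' Metabolites passing the QC filters
#'
#' @param report A [qc_report()].
#' @return Character vector of kept metabolite names, in panel order.
#' @export
filter_metabolites <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  report$metabolite[report$verdict == "kept"]
}

#' Subset a metabolite matrix to QC-passing metabolites
#'
#' @param mm A `metabolite_matrix`.
#' @param report A [qc_report()] for the same panel.
#' @return The `metabolite_matrix` restricted to kept metabolites.
#' @export
apply_qc_filter <- function(mm, report = qc_report(mm)) {
  stopifnot(inherits(mm, "metabolite_matrix"))
  keep <- filter_metabolites(report)
  mm$concentrations <- mm$concentrations[, keep, drop = FALSE]
  mm$below_lod <- mm$below_lod[, keep, drop = FALSE]
  mm$qc <- mm$qc[, keep, drop = FALSE]
  mm$meta <- mm$meta[mm$meta$metabolite %in% keep, , drop = FALSE]
  mm
}

#' Impute below-LOD measurements with the lowest observed concentration
#'
#' Each below-LOD cell is replaced by the minimum detected (non-flagged)
#' concentration of that metabolite across the study samples; no other cell is
#' modified. A metabolite with no detected values at all has no observed
#' minimum and raises an error.
#'
#' @param mm A `metabolite_matrix`.
#' @return The `metabolite_matrix` with imputed concentrations; the
#'   `below_lod` flags are retained and an `n_imputed` attribute is added to
#'   the concentration matrix.
#' @export
impute_lod <- function(mm) {
  stopifnot(inherits(mm, "metabolite_matrix"))
  conc <- mm$concentrations
  flags <- mm$below_lod
  n_imp <- 0L
  for (j in seq_len(ncol(conc))) {
    f <- flags[, j]
    if (!any(f)) next
    obs <- conc[!f, j]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0L)
      stop(sprintf("metabolite %s has no detected values; cannot impute LOD",
                   colnames(conc)[j]))
    conc[f, j] <- min(obs)
    n_imp <- n_imp + sum(f)
  }
  attr(conc, "n_imputed") <- n_imp
  mm$concentrations <- conc
  mm
}

#' Log-transform and z-score a metabolite matrix
#'
#' Each metabolite is natural-log-transformed, then standardized by
#' subtracting its mean and dividing by its sample SD (denominator `n - 1`),
#' both computed on the supplied analysis sample. Constant columns (SD zero)
#' are degenerate: they are returned as `NA` and listed in the `degenerate`
#' attribute with a warning. Non-positive concentrations are an error (run
#' [impute_lod()] first).
#'
#' @param mm A `metabolite_matrix` or a numeric matrix of concentrations.
#' @return A numeric matrix of standardized log-concentrations with the same
#'   dimnames.
#' @export
transform_metabolites <- function(mm) {
  conc <- if (inherits(mm, "metabolite_matrix")) mm$concentrations else mm
  stopifnot(is.matrix(conc))
  bad <- which(conc <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive concentration for metabolite %s (row %d)",
                 colnames(conc)[bad[1, 2]], bad[1, 1]))
  lg <- log(conc)
  mu <- colMeans(lg, na.rm = TRUE)
  sdv <- apply(lg, 2L, stats::sd, na.rm = TRUE)
  degenerate <- colnames(conc)[!is.na(sdv) & sdv == 0]
  sdv[sdv == 0] <- NA_real_
  z <- sweep(sweep(lg, 2L, mu, `-`), 2L, sdv, `/`)
  if (length(degenerate) > 0) {
    warning("degenerate (constant) metabolite columns set to NA: ",
            paste(degenerate, collapse = ", "))
  }
  attr(z, "degenerate") <- degenerate
  z
}

#' Log-transform lipid and cardiometabolic traits
#'
#' Natural-log-transforms TG, TC, LDL_C, HDL_C, GLU, HbA1c, HOMA_IR, UA and
#' hsCRP; SBP and DBP are left on the raw scale. Missing values propagate
#' unchanged. Non-positive values cannot be logged: they are set to `NA`
#' (complete-case handling downstream) and counted in the `n_nonpositive`
#' attribute.
#'
#' @param cohort A cohort data.frame.
#' @return The cohort with transformed traits; attributes `log_traits` and
#'   `n_nonpositive` record what was done.
#' @export
transform_traits <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  nonpos <- integer(0)
  for (tr in intersect(.LOG_TRAITS, names(cohort))) {
    v <- cohort[[tr]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      nonpos[tr] <- sum(bad)
      v[bad] <- NA_real_
    }
    cohort[[tr]] <- log(v)
  }
  attr(cohort, "log_traits") <- intersect(.LOG_TRAITS, names(cohort))
  attr(cohort, "n_nonpositive") <- nonpos
  cohort
}

#' Per-trait completeness report
#'
#' @param cohort A cohort data.frame.
#' @param traits Trait columns to tally (default: all lipids and
#'   cardiometabolic traits present, plus BMI).
#' @return data.frame with columns `trait`, `n_observed`, `n_missing`.
#' @export
completeness_report <- function(cohort,
                                traits = intersect(c(.LIPIDS, .CM_TRAITS, "BMI"),
                                                   names(cohort))) {
  data.frame(trait = traits,
             n_observed = vapply(traits, function(tr) sum(!is.na(cohort[[tr]])),
                                 integer(1)),
             n_missing = vapply(traits, function(tr) sum(is.na(cohort[[tr]])),
                                integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
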