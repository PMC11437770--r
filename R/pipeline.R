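#' Default pipeline configuration
#'
#' All analysis thresholds are surfaced here (none are hidden in the code):
#' the 30% analytical-CV filter, the 50% QC-occurrence filter, the 5% FDR for
#' the association screen, the 5% alpha for ICE FALCON and mediation, and the
#' 24 kg/m^2 BMI overweight cutoff.
#'
#' @param seed Master seed.
#' @return Nested configuration list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      cohort = list(n_pairs = 210L, n_singletons = 17L),
      metabolome = list(n_metabolites = 60L)
    ),
    thresholds = list(cv = 0.30, occurrence = 0.50, fdr = 0.05, alpha = 0.05,
                      bmi_cutoff = 24),
    association = list(engine = "lmm", adjust_bmi = FALSE),
    falcon = list(enabled = TRUE, B = 200L, top_n = 2L),
    mediation = list(enabled = TRUE, n_sims = 500L, direction = NULL,
                     traits = c("GLU", "HbA1c", "HOMA_IR", "SBP", "DBP",
                                "UA", "hsCRP"))
  )
}

# Deep-merge user config over defaults.
.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Keys present in the file override [default_config()]; everything else keeps
#' its default.
#'
#' @param path YAML file path.
#' @param seed Master seed (overrides the file's `seed` if given).
#' @return Configuration list.
#' @export
read_config <- function(path, seed = NULL) {
  cfg <- .merge_config(default_config(), yaml::read_yaml(path))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8", eol = "\n")
}

#' Write / read a cohort as RFC-4180 CSV
#'
#' Missing values are encoded as empty fields.
#'
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @return `read_cohort_csv` returns the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(individual_id = "character",
                                 pair_id = "character"))
}

#' Descriptive summary table for a twin cohort
#'
#' Mean (SD) for age, BMI, SBP and DBP; median (IQR, type-7 linear
#' interpolation quartiles) for the lipids and the remaining cardiometabolic
#' traits; n (%) for gender and region; per-trait missing counts.
#'
#' @param cohort Cohort data.frame on the raw measurement scale.
#' @return data.frame with `characteristic`, `type`, `v1`, `v2`, `v3`
#'   (numeric summaries: mean/median, SD/Q1, Q3), `n_missing` and a formatted
#'   `label`.
#' @export
summarize_cohort <- function(cohort) {
  mean_traits <- intersect(c("age", "BMI", "SBP", "DBP"), names(cohort))
  med_traits <- intersect(c("TG", "TC", "LDL_C", "HDL_C", "GLU", "HbA1c",
                            "HOMA_IR", "UA", "hsCRP"), names(cohort))
  rows <- list()
  n <- nrow(cohort)
  rows[[length(rows) + 1L]] <- data.frame(
    characteristic = "n", type = "count", v1 = n, v2 = NA_real_,
    v3 = NA_real_, n_missing = 0L, label = sprintf("%d", n))
  for (cat_col in c("gender", "region")) {
    if (!cat_col %in% names(cohort)) next
    lev <- if (cat_col == "gender") "female" else "southern"
    k <- sum(cohort[[cat_col]] == lev, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = paste0(cat_col, ":", lev), type = "n_pct",
      v1 = k, v2 = 100 * k / n, v3 = NA_real_,
      n_missing = sum(is.na(cohort[[cat_col]])),
      label = sprintf("%d (%.1f%%)", k, 100 * k / n))
  }
  for (tr in mean_traits) {
    v <- cohort[[tr]]
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = tr, type = "mean_sd",
      v1 = mean(v, na.rm = TRUE), v2 = stats::sd(v, na.rm = TRUE),
      v3 = NA_real_, n_missing = sum(is.na(v)),
      label = sprintf("%.2f (%.2f)", mean(v, na.rm = TRUE),
                      stats::sd(v, na.rm = TRUE)))
  }
  for (tr in med_traits) {
    v <- cohort[[tr]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7,
                         names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = tr, type = "median_iqr",
      v1 = q[2], v2 = q[1], v3 = q[3], n_missing = sum(is.na(v)),
      label = sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full twin metabolomics pipeline
#'
#' Executes simulate -> preprocess -> associate -> ICE FALCON -> mediation
#' from one configuration and one master seed, writing stage outputs and a
#' run manifest to `out_dir`. Stage counts form a conservation chain
#' (assayed -> kept -> associated -> causally probed -> mediation triplets ->
#' linkages) recorded in the manifest. If the ICE FALCON stage is disabled,
#' the mediation stage refuses to auto-orient and requires an explicit
#' `mediation$direction` (`"lipid_to_metabolite"` or `"metabolite_to_lipid"`)
#' in the configuration.
#'
#' @param config Configuration list (see [default_config()]) or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master-seed override.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- .merge_config(default_config(), config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  stage <- "simulate"
  result <- tryCatch({
    ## 1. simulate
    cspec <- do.call(twin_cohort_spec,
                     c(config$simulate$cohort, list(seed = config$seed)))
    sim <- simulate_twin_cohort(cspec)
    mspec <- do.call(metabolome_spec, config$simulate$metabolome)
    mm <- simulate_metabolome(sim, mspec)
    write_cohort_csv(sim$cohort, file.path(out_dir, "cohort.csv"))
    write_cohort_csv(sim$truth, file.path(out_dir, "truth_sidecar.csv"))
    utils::write.csv(data.frame(individual_id = rownames(mm$concentrations),
                                mm$concentrations, check.names = FALSE),
                     file.path(out_dir, "metabolites.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(data.frame(qc_injection = rownames(mm$qc), mm$qc,
                                check.names = FALSE),
                     file.path(out_dir, "qc.csv"), row.names = FALSE, na = "")

    ## 2. preprocess
    stage <- "preprocess"
    rep_qc <- qc_report(mm, cv_threshold = th$cv,
                        occurrence_threshold = th$occurrence)
    .write_tsv(rep_qc, file.path(out_dir, "qc_report.tsv"))
    mm_kept <- apply_qc_filter(mm, rep_qc)
    mm_imp <- impute_lod(mm_kept)
    met_z <- transform_metabolites(mm_imp)
    cohort_t <- transform_traits(sim$cohort)
    .write_tsv(completeness_report(sim$cohort),
               file.path(out_dir, "completeness.tsv"))
    .write_tsv(summarize_cohort(sim$cohort),
               file.path(out_dir, "cohort_summary.tsv"))

    ## 3. associate
    stage <- "associate"
    assoc <- associate(cohort_t, met_z,
                       adjust_bmi = isTRUE(config$association$adjust_bmi),
                       engine = config$association$engine,
                       fdr_threshold = th$fdr)
    .write_tsv(assoc, file.path(out_dir, "associations.tsv"))

    ## 4. ICE FALCON on the top associated metabolites per lipid
    stage <- "falcon"
    falcon_rows <- NULL
    falcon_results <- list()
    if (isTRUE(config$falcon$enabled)) {
      sig <- assoc[order(assoc$q_value), ]
      sig <- sig[!is.na(sig$q_value), ]
      picks <- do.call(rbind, lapply(split(sig, sig$lipid), function(d)
        utils::head(d, config$falcon$top_n)))
      for (k in seq_len(nrow(picks))) {
        met <- picks$metabolite[k]; lip <- picks$lipid[k]
        dat <- cohort_t
        dat[[met]] <- met_z[match(dat$individual_id, rownames(met_z)), met]
        fr <- tryCatch(
          ice_falcon(dat, x_name = met, y_name = lip, B = config$falcon$B,
                     seed = .substream(config$seed, 400L + k),
                     alpha = th$alpha),
          error = function(e) NULL)
        if (is.null(fr)) next
        falcon_results[[paste(met, lip, sep = "|")]] <- fr
        falcon_rows <- rbind(falcon_rows, as.data.frame(fr))
      }
      if (!is.null(falcon_rows))
        .write_tsv(falcon_rows, file.path(out_dir, "icefalcon.tsv"))
    }

    ## 5. mediation
    stage <- "mediate"
    med_rows <- NULL
    med_pairs <- list()
    n_screened <- 0L
    if (isTRUE(config$mediation$enabled)) {
      direction <- config$mediation$direction
      lip_to_met <- NULL
      if (isTRUE(config$falcon$enabled)) {
        # auto-orient: lipid -> metabolite where the classifier said so
        # (x = metabolite, y = lipid, so Y_to_X means lipid causes metabolite)
        lip_to_met <- vapply(falcon_results, function(fr)
          fr$classification == "consistent_causal_Y_to_X", logical(1))
      } else if (is.null(direction)) {
        stop("mediation requires an explicit `mediation$direction` when the ",
             "ICE FALCON stage is disabled (no causal orientation available)")
      }
      traits <- intersect(config$mediation$traits, names(cohort_t))
      scr <- prescreen_pearson(met_z,
                               cohort_t[match(rownames(met_z),
                                              cohort_t$individual_id),
                                        traits, drop = FALSE])
      candidates <- if (isTRUE(config$falcon$enabled)) {
        if (identical(direction, "lipid_to_metabolite"))
          names(falcon_results)
        else names(falcon_results)[lip_to_met]
      } else {
        # explicit direction, no causal screen: take the top association
        # per lipid as exposure -> mediator candidates
        sig <- assoc[!is.na(assoc$q_value), ]
        sig <- sig[order(sig$q_value), ]
        picks <- do.call(rbind, lapply(split(sig, sig$lipid), function(d)
          utils::head(d, 1L)))
        paste(picks$metabolite, picks$lipid, sep = "|")
      }
      dat_all <- cohort_t
      for (key in candidates) {
        parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
        met <- parts[1L]; lip <- parts[2L]
        dat_all[[met]] <- met_z[match(dat_all$individual_id,
                                      rownames(met_z)), met]
        elig <- scr$trait[scr$metabolite == met & scr$eligible]
        for (tr in elig) {
          n_screened <- n_screened + 1L
          mp <- bidirectional_mediation(
            dat_all, exposure = lip, mediator = met, outcome = tr,
            n_sims = config$mediation$n_sims,
            seed = .substream(config$seed, 500L + n_screened),
            alpha = th$alpha)
          med_pairs[[paste(lip, met, tr, sep = "|")]] <- mp
          med_rows <- rbind(med_rows, as.data.frame(mp))
        }
      }
      if (!is.null(med_rows))
        .write_tsv(med_rows, file.path(out_dir, "mediation.tsv"))
    }

    ## manifest
    stage <- "manifest"
    n_linkages <- sum(vapply(med_pairs, function(mp)
      mp$verdict == "linkage", logical(1)))
    manifest <- list(
      package_version = as.character(utils::packageVersion("twinfalcon")),
      seed = config$seed,
      thresholds = th,
      bootstrap_B = config$falcon$B,
      mediation_sims = config$mediation$n_sims,
      counts = list(
        individuals = nrow(sim$cohort),
        pairs = cspec$n_pairs, singletons = cspec$n_singletons,
        metabolites_assayed = ncol(mm$concentrations),
        metabolites_kept = ncol(met_z),
        associations_tested = nrow(assoc),
        associations_significant = sum(assoc$significant, na.rm = TRUE),
        falcon_tested = length(falcon_results),
        mediation_triplets_screened = n_screened,
        mediation_linkages = n_linkages))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    list(config = config, cohort = sim$cohort, qc_report = rep_qc,
         met_z = met_z, associations = assoc, falcon = falcon_results,
         mediation = med_pairs, manifest = manifest, out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
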