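# Shared simulation helpers for the test suite.

# Cohort under a named structural scenario, with the standardized target
# lipid and the structural metabolite merged in as analysis columns.
scenario_data <- function(seed, scenario = c("causal", "confounding",
                                             "null", "independent"),
                          n_pairs = 1000L, n_singletons = 0L) {
  scenario <- match.arg(scenario)
  par <- switch(scenario,
    causal      = list(lx = 0.7, ly = 0, b = 0.3, dir = "x_to_y"),
    confounding = list(lx = 0.7, ly = 0.7, b = 0, dir = "none"),
    null        = list(lx = 0.7, ly = 0, b = 0, dir = "none"),
    independent = list(lx = 0, ly = 0, b = 0, dir = "none"))
  sim <- simulate_twin_cohort(twin_cohort_spec(
    n_pairs = n_pairs, n_singletons = n_singletons,
    familial_loading_x = par$lx, familial_loading_y = par$ly,
    causal_effect = par$b, causal_direction = par$dir,
    missing_counts = NULL, seed = seed))
  mm <- simulate_metabolome(sim, metabolome_spec(
    n_metabolites = 1L, lod_quantile = 0, frac_high_cv = 0,
    frac_low_occurrence = 0))
  z <- transform_metabolites(mm)
  dat <- transform_traits(sim$cohort)
  dat$met <- z[match(dat$individual_id, rownames(z)), 1L]
  dat$lipid_z <- as.numeric(scale(dat$TG))
  dat$met_z <- as.numeric(scale(dat$met))
  dat
}

# Small metabolite_matrix built by hand for preprocessing unit tests.
toy_metabolome <- function(conc, below = NULL, qc = NULL) {
  conc <- as.matrix(conc)
  if (is.null(rownames(conc))) rownames(conc) <- paste0("i", seq_len(nrow(conc)))
  if (is.null(colnames(conc))) colnames(conc) <- paste0("m", seq_len(ncol(conc)))
  if (is.null(below)) below <- matrix(FALSE, nrow(conc), ncol(conc),
                                      dimnames = dimnames(conc))
  if (is.null(qc)) qc <- matrix(1, 3, ncol(conc),
                                dimnames = list(NULL, colnames(conc)))
  structure(list(concentrations = conc, below_lod = below, qc = qc,
                 meta = data.frame(metabolite = colnames(conc),
                                   class = "amino acids",
                                   gut_microbiota = FALSE),
                 qc_truth = NULL, spec = NULL),
            class = "metabolite_matrix")
}
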