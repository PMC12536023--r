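#' Read a long-format PAF table
#'
#' Reads a CSV with one row per subject x macro-region x condition.
#' Required columns: `subject`, `diagnosis`, `condition`, `region`,
#' `paf_hz`, `age_months`, `sex`, `srs_total`; extra columns are preserved.
#' Duplicate subject-region-condition keys are rejected.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_paf_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_paf_table(tab)
}

#' @rdname read_paf_table
#' @param table A PAF table data frame.
#' @export
validate_paf_table <- function(table) {
  req <- c("subject", "diagnosis", "condition", "region", "paf_hz",
           "age_months", "sex", "srs_total")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stop("PAF table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  key <- paste(table$subject, table$region, table$condition, sep = "|")
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("duplicate subject x region x condition key(s): ",
         paste(unique(head(dup, 3)), collapse = ", "))
  bad_cond <- setdiff(unique(table$condition), c("DR", "EO"))
  if (length(bad_cond))
    stop("condition must be DR or EO; found: ",
         paste(bad_cond, collapse = ", "))
  table
}

#' @rdname read_paf_table
#' @export
write_paf_table <- function(table, path) {
  validate_paf_table(table)
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the simulate-estimate-aggregate-analyse
#' pipeline.  The defaults reproduce the reference analysis protocol:
#' 5-s epochs with 80% overlap and a Hamming taper, at least 10 epochs,
#' aperiodic fit over 1-55 Hz with Huber M = 1.35, alpha band 7-13 Hz, and
#' Bonferroni gates over 5 region families (0.01) and 2 subgroup
#' comparisons (0.025).
#'
#' @param spectral A [spectral_config()].
#' @param fit_range Aperiodic fit range in Hz.
#' @param band Alpha band in Hz.
#' @param huber_m Huber tuning constant.
#' @param design A [cohort_design()] for simulate mode.
#' @param n_region_comparisons,n_subgroup_comparisons Bonferroni families.
#' @param region_map_path Optional override path for [load_region_map()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spectral = spectral_config(),
                            fit_range = c(1, 55), band = c(7, 13),
                            huber_m = 1.35,
                            design = cohort_design(),
                            n_region_comparisons = 5,
                            n_subgroup_comparisons = 2,
                            region_map_path = NULL) {
  stopifnot(inherits(spectral, "spectral_config"),
            inherits(design, "cohort_design"),
            length(fit_range) == 2, fit_range[1] > 0,
            fit_range[2] > fit_range[1],
            length(band) == 2, band[1] < band[2],
            huber_m > 0, n_region_comparisons >= 1,
            n_subgroup_comparisons >= 1)
  structure(list(spectral = spectral, fit_range = fit_range, band = band,
                 huber_m = huber_m, design = design,
                 n_region_comparisons = n_region_comparisons,
                 n_subgroup_comparisons = n_subgroup_comparisons,
                 region_map_path = region_map_path),
            class = "pipeline_config")
}

# Small stable FNV-1a hash of a deparsed object, for run manifests.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(h, b)) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

#' Estimate PAF for every cell of a synthetic cohort
#'
#' Synthesises a region-level power spectrum from each cell's generative
#' parameters and runs [estimate_paf()] on it.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config A [pipeline_config()].
#' @param seed Optional integer seed for the spectral noise.
#' @return Data frame keyed by `subject`, `region`, `condition` with
#'   columns `status`, `paf_hz`, `amplitude`, `width_hz`, `slope`,
#'   `intercept`, `r2`.
#' @export
estimate_cohort_paf <- function(cohort, config = pipeline_config(),
                                seed = NULL) {
  stopifnot(inherits(cohort, "paf_cohort"))
  sp <- cohort$spectra_params
  freqs <- seq(0.2, max(config$fit_range), by = 0.2)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(sp)), function(i) {
      p <- spectral_params(offset = sp$offset[i], exponent = sp$exponent[i],
                           peak_center = sp$peak_center[i],
                           peak_amplitude = sp$peak_amplitude[i],
                           peak_width = sp$peak_width[i],
                           noise_sd = sp$noise_sd[i])
      fit <- estimate_paf(synth_psd(p, freqs),
                          fit_range = config$fit_range, band = config$band,
                          huber_m = config$huber_m)
      data.frame(subject = sp$subject[i], region = sp$region[i],
                 condition = sp$condition[i], status = fit$status,
                 paf_hz = fit$paf,
                 amplitude = if (fit$status == "present")
                   fit$peak$amplitude else NA_real_,
                 width_hz = if (fit$status == "present")
                   fit$peak$width else NA_real_,
                 slope = fit$aperiodic$slope,
                 intercept = fit$aperiodic$intercept, r2 = fit$r2,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Run the full analysis battery on a PAF table
#'
#' Fits the reactivity mixed model in every macro-region present, applies
#' the Bonferroni region gate to the interaction p-values, runs subgroup
#' models where the gate opens, and fits the change-score and (for gated
#' regions) SRS-association regressions.
#'
#' @param table A PAF table.
#' @param config A [pipeline_config()].
#' @return List with `reactivity` (named list of `paf_model`),
#'   `interaction_gate` (logical per region), `subgroup`, `change_score`
#'   and `srs` model lists.
#' @export
analyze_paf_table <- function(table, config = pipeline_config()) {
  validate_paf_table(table)
  regions <- intersect(macro_regions(), unique(table$region))
  reactivity <- lapply(setNames(regions, regions),
                       function(r) fit_reactivity_lmm(table, r))
  p_int <- vapply(reactivity, function(m) {
    tab <- m$coefficients
    tab$p[grepl(":", tab$term)]
  }, numeric(1))
  gate <- bonferroni_gate(p_int, config$n_region_comparisons)
  gated <- regions[gate]
  subgroup <- lapply(setNames(gated, gated), function(r)
    list(TD = fit_subgroup_lmm(table, r, "TD"),
         ASD = fit_subgroup_lmm(table, r, "ASD")))
  change <- lapply(setNames(regions, regions),
                   function(r) change_score_regression(table, r))
  srs <- lapply(setNames(gated, gated),
                function(r) srs_association(table, r))
  list(reactivity = reactivity, interaction_p = p_int,
       interaction_gate = gate, subgroup = subgroup,
       change_score = change, srs = srs)
}

model_to_df <- function(m, region, extra = list()) {
  tab <- m$coefficients
  tab$region <- region
  for (nm in names(extra)) tab[[nm]] <- extra[[nm]]
  tab
}

#' Run the full pipeline into a run directory
#'
#' Simulates a cohort, synthesises and estimates region spectra, applies
#' the missing-if-absent aggregation rule, analyses the resulting PAF
#' table, and writes every artifact plus a JSON manifest to `out_dir`.
#' Given the same config and seed the run directory contents are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; must not contain a previous
#'   manifest unless `overwrite = TRUE`).
#' @param seed Integer seed driving all randomness.
#' @param estimate_spectra If `TRUE` (default), PAF values are re-estimated
#'   from synthesised spectra; if `FALSE`, the generator's table is
#'   analysed directly (fast path).
#' @param overwrite Allow writing into an existing run directory.
#' @return Invisibly, a list with the cohort, the analysed table, the
#'   analysis results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1,
                         estimate_spectra = TRUE, overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) &&
      file.exists(file.path(out_dir, "manifest.json")) && !overwrite)
    stop("run directory already contains a manifest; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(config$design, seed = seed)
  write_paf_table(cohort$table, file.path(out_dir, "cohort_true.csv"))

  if (estimate_spectra) {
    est <- estimate_cohort_paf(cohort, config, seed = seed + 1L)
    write.csv(est, file.path(out_dir, "paf_estimates.csv"),
              row.names = FALSE, quote = FALSE)
    # aggregation: one spectrum per macro-region cell, so the
    # missing-if-no-valid-estimate rule reduces to dropping absent cells
    tab <- cohort$table
    key_t <- paste(tab$subject, tab$region, tab$condition)
    key_e <- paste(est$subject, est$region, est$condition)
    tab$paf_hz <- est$paf_hz[match(key_t, key_e)]
  } else {
    tab <- cohort$table
  }
  write_paf_table(tab, file.path(out_dir, "paf_table.csv"))

  analysis <- analyze_paf_table(tab, config)
  react_df <- do.call(rbind, lapply(names(analysis$reactivity), function(r)
    model_to_df(analysis$reactivity[[r]], r)))
  write.csv(react_df, file.path(out_dir, "reactivity_models.csv"),
            row.names = FALSE, quote = FALSE)
  change_df <- do.call(rbind, lapply(names(analysis$change_score),
                                     function(r)
    model_to_df(analysis$change_score[[r]], r)))
  write.csv(change_df, file.path(out_dir, "change_score_models.csv"),
            row.names = FALSE, quote = FALSE)
  if (length(analysis$srs)) {
    srs_df <- do.call(rbind, lapply(names(analysis$srs), function(r)
      model_to_df(analysis$srs[[r]], r)))
    write.csv(srs_df, file.path(out_dir, "srs_models.csv"),
              row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pafreact")),
    seed = seed, config_hash = config_hash(config),
    estimate_spectra = estimate_spectra,
    settings = list(epoch_seconds = config$spectral$epoch_seconds,
                    overlap_fraction = config$spectral$overlap_fraction,
                    min_epochs = config$spectral$min_epochs,
                    fit_range = config$fit_range, band = config$band,
                    huber_m = config$huber_m,
                    n_region_comparisons = config$n_region_comparisons,
                    n_subgroup_comparisons = config$n_subgroup_comparisons),
    rows = list(paf_table = nrow(tab),
                subjects = length(unique(tab$subject)),
                reactivity_terms = nrow(react_df),
                change_terms = nrow(change_df)),
    gated_regions = names(analysis$interaction_gate)[analysis$interaction_gate])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, table = tab, analysis = analysis,
                 manifest = manifest))
}
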