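#' Load the micro- to macro-region map
#'
#' Returns the mapping of the 68 Desikan-Killiany cortical parcels to the
#' 10 lobe-by-hemisphere macro-regions (cingulate, frontal, occipital,
#' parietal, temporal in each hemisphere).  Per hemisphere the lobes hold
#' 4, 11, 4, 5 and 10 parcels respectively; the temporal count includes the
#' insula, which sits on no classical lobe and is assigned to the adjacent
#' temporal group (override the shipped table to place it elsewhere).
#'
#' @param path Optional path to a tab- or comma-delimited override file
#'   with columns `micro`, `hemisphere`, `lobe`.  The override must still
#'   describe exactly 68 unique parcels mapping onto 10 macro-regions with
#'   mirror-symmetric hemispheres.
#' @return An object of class `region_map`: a data frame with columns
#'   `micro`, `hemisphere`, `lobe` and `region` (`lobe_hemisphere`).
#' @examples
#' map <- load_region_map()
#' table(map$lobe, map$hemisphere)
#' @export
load_region_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dk_macro_regions.tsv",
                        package = "pafreact", mustWork = TRUE)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  map <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  req <- c("micro", "hemisphere", "lobe")
  if (!all(req %in% names(map)))
    stop("region map must have columns: ", paste(req, collapse = ", "))
  if (nrow(map) != 68)
    stop(sprintf("region map must contain exactly 68 parcels, got %d",
                 nrow(map)))
  if (anyDuplicated(map$micro))
    stop("duplicate micro-region names in region map")
  map$region <- paste(map$lobe, map$hemisphere, sep = "_")
  if (length(unique(map$region)) != 10)
    stop("region map must define exactly 10 macro-regions")
  counts <- table(map$lobe, map$hemisphere)
  if (ncol(counts) != 2 || any(counts[, 1] != counts[, 2]))
    stop("left/right macro-region assignments must be mirror-symmetric")
  structure(map, class = c("region_map", "data.frame"))
}

#' Aggregate micro-region PAF estimates into macro-regions
#'
#' Averages valid (present) micro-region PAF estimates within each
#' macro-region.  Absent estimates are excluded from the mean; a
#' macro-region with no valid micro-region estimate is returned with a
#' missing PAF.  Averaging only valid parcels means a macro-region survives
#' as long as at least one of its parcels produced an in-band peak.
#'
#' @param micro_estimates Data frame with columns `micro` and `paf_hz`
#'   (`NA` = absent), plus optional grouping columns (e.g. `subject`,
#'   `condition`) which are carried through and aggregated within.
#' @param map A [load_region_map()] table.
#' @return Data frame with one row per macro-region (per group), columns
#'   `hemisphere`, `lobe`, `region`, `paf_hz`, `n_valid_micro`,
#'   `n_total_micro`.
#' @examples
#' map <- load_region_map()
#' est <- data.frame(micro = map$micro, paf_hz = 9.8)
#' head(aggregate_macro(est, map))
#' @export
aggregate_macro <- function(micro_estimates, map = load_region_map()) {
  stopifnot(is.data.frame(micro_estimates),
            all(c("micro", "paf_hz") %in% names(micro_estimates)))
  unknown <- setdiff(micro_estimates$micro, map$micro)
  if (length(unknown))
    stop("unknown micro-region label(s): ",
         paste(head(unknown, 5), collapse = ", "))
  idx <- match(micro_estimates$micro, map$micro)
  df <- micro_estimates
  df$region <- map$region[idx]
  group_cols <- setdiff(names(micro_estimates), c("micro", "paf_hz"))
  key <- if (length(group_cols))
    interaction(df[c("region", group_cols)], drop = FALSE, lex.order = TRUE)
  else df$region
  pieces <- split(df, key, drop = TRUE)
  out <- do.call(rbind, lapply(pieces, function(g) {
    valid <- !is.na(g$paf_hz)
    row <- g[1, group_cols, drop = FALSE]
    row$region <- g$region[1]
    row$paf_hz <- if (any(valid)) mean(g$paf_hz[valid]) else NA_real_
    row$n_valid_micro <- sum(valid)
    row$n_total_micro <- nrow(g)
    row
  }))
  out$hemisphere <- sub("^.*_", "", out$region)
  out$lobe <- sub("_.*$", "", out$region)
  out <- out[c(group_cols, "hemisphere", "lobe", "region", "paf_hz",
               "n_valid_micro", "n_total_micro")]
  rownames(out) <- NULL
  out
}

#' Proportion of valid PAF estimates
#'
#' The percentage of micro-region PAF estimates that fell inside the alpha
#' band, out of all parcel-by-participant observations for one group,
#' macro-region and condition: `100 * n_present / (n_micro * n_subjects)`.
#'
#' @param n_present Number of valid (in-band) estimates.
#' @param n_micro Number of parcels in the macro-region.
#' @param n_subjects Number of participants contributing.
#' @return Percentage in `[0, 100]`.
#' @export
validity_proportion <- function(n_present, n_micro, n_subjects) {
  stopifnot(n_micro >= 1, n_subjects >= 1, n_present >= 0,
            n_present <= n_micro * n_subjects)
  100 * n_present / (n_micro * n_subjects)
}

#' Validity proportions for a micro-level estimate table
#'
#' Tabulates [validity_proportion()] for every diagnosis x macro-region x
#' condition cell of a micro-level estimate table, using the full parcel
#' count of each macro-region times the number of participants as the
#' denominator.
#'
#' @param micro_estimates Data frame with columns `subject`, `diagnosis`,
#'   `condition`, `micro`, `paf_hz` (`NA` = absent).
#' @param map A [load_region_map()] table.
#' @return Data frame with columns `diagnosis`, `condition`, `region`,
#'   `n_present`, `n_micro`, `n_subjects`, `validity_pct`.
#' @export
validity_table <- function(micro_estimates, map = load_region_map()) {
  stopifnot(all(c("subject", "diagnosis", "condition", "micro", "paf_hz")
                %in% names(micro_estimates)))
  df <- micro_estimates
  idx <- match(df$micro, map$micro)
  if (anyNA(idx))
    stop("unknown micro-region label(s) in estimate table")
  df$region <- map$region[idx]
  n_micro_by_region <- table(map$region)
  pieces <- split(df, df[c("diagnosis", "condition", "region")], drop = TRUE)
  out <- do.call(rbind, lapply(pieces, function(g) {
    n_subj <- length(unique(g$subject))
    n_mic <- as.integer(n_micro_by_region[[g$region[1]]])
    data.frame(diagnosis = g$diagnosis[1], condition = g$condition[1],
               region = g$region[1], n_present = sum(!is.na(g$paf_hz)),
               n_micro = n_mic, n_subjects = n_subj,
               validity_pct = validity_proportion(sum(!is.na(g$paf_hz)),
                                                  n_mic, n_subj),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
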