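# Protein-groups ingestion: read the MaxQuant-style table, strip decoys and
# contaminants, log2-transform into a long intensity tibble, apply the
# valid-value filter and impute censored values from a downshifted normal.

REQUIRED_PG_COLUMNS <- c("Majority protein IDs", "Reverse", "Potential contaminant")

#' Read a MaxQuant-style protein-groups table
#'
#' Reads a TSV protein-groups table, checking for the required columns
#' (`Majority protein IDs`, `Reverse`, `Potential contaminant` and at least
#' one `LFQ intensity <sample>` column). Zero and empty LFQ cells are
#' converted to `NA`, following the MaxQuant convention that an LFQ intensity
#' of 0 means "not quantified". Majority-ID strings are preserved verbatim.
#'
#' @param path Path to the TSV file.
#' @return A tibble, one row per protein group, with numeric LFQ columns.
#' @export
read_protein_groups <- function(path) {
  if (!file.exists(path)) {
    abort_input(paste0("file not found: ", path))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = character())
  missing <- setdiff(REQUIRED_PG_COLUMNS, names(tab))
  if (length(missing) > 0) {
    abort_format(paste0("protein-groups table lacks required column '",
                        missing[1], "'"))
  }
  lfq_cols <- grep("^LFQ intensity ", names(tab), value = TRUE)
  if (length(lfq_cols) == 0) {
    abort_format("protein-groups table has no 'LFQ intensity <sample>' columns")
  }
  for (cl in lfq_cols) {
    vals <- trimws(tab[[cl]])
    empty <- !nzchar(vals) | is.na(vals)
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!empty & is.na(num))
    if (length(bad) > 0) {
      abort_format(paste0("unreadable numeric in column '", cl,
                          "', row ", bad[1]))
    }
    num[empty | num == 0] <- NA_real_
    tab[[cl]] <- num
  }
  tab
}

new_filter_report <- function(n_input) {
  tibble::tibble(
    n_input = n_input, n_reverse_removed = 0L, n_contaminant_removed = 0L,
    n_failed_valid_filter = 0L, n_retained = n_input
  )
}

#' Filter report of an ingest object
#'
#' Bookkeeping carried along by [remove_decoys_and_contaminants()] and
#' [valid_value_filter()]: input count, reverse/contaminant removals,
#' valid-value-filter failures, and the retained count (which always equals
#' the input count minus all removals).
#'
#' @param x A table or intensity tibble produced by the ingest functions.
#' @return A one-row tibble.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report") %||% new_filter_report(NA_integer_)
}

#' Remove reverse-database and contaminant entries
#'
#' Drops rows flagged `+` in the `Reverse` or `Potential contaminant` columns
#' of a protein-groups table. A row flagged as both is counted once, under
#' reverse. Removal counts are recorded in the attached [filter_report()].
#'
#' @param tab A protein-groups tibble from [read_protein_groups()].
#' @return The filtered tibble with an updated `filter_report` attribute.
#' @export
remove_decoys_and_contaminants <- function(tab) {
  missing <- setdiff(c("Reverse", "Potential contaminant"), names(tab))
  if (length(missing) > 0) {
    abort_format(paste0("table lacks flag column '", missing[1], "'"))
  }
  is_rev <- !is.na(tab$Reverse) & trimws(tab$Reverse) == "+"
  is_con <- !is_rev & !is.na(tab$`Potential contaminant`) &
    trimws(tab$`Potential contaminant`) == "+"
  report <- filter_report(tab)
  if (is.na(report$n_input)) report$n_input <- nrow(tab)
  report$n_reverse_removed <- report$n_reverse_removed + sum(is_rev)
  report$n_contaminant_removed <- report$n_contaminant_removed + sum(is_con)
  report$n_retained <- nrow(tab) - sum(is_rev) - sum(is_con)
  out <- tab[!is_rev & !is_con, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Pivot a protein-groups table into a long intensity tibble
#'
#' Log2-transforms the LFQ columns and reshapes them into the long format the
#' rest of the pipeline consumes: one row per protein x sample with the log2
#' intensity, an `observed` flag (a measured value was present) and an
#' `imputed` flag (filled later by [impute_missing()]). The condition of each
#' sample is taken from the sample name prefix before the final `_<replicate>`.
#'
#' @param tab A protein-groups tibble (decoys/contaminants usually already
#'   removed).
#' @return A long tibble with columns `protein_id`, `sample_id`, `condition`,
#'   `log2_intensity`, `observed`, `imputed`; the `filter_report` attribute is
#'   carried over.
#' @export
pivot_intensities <- function(tab) {
  lfq_cols <- grep("^LFQ intensity ", names(tab), value = TRUE)
  if (length(lfq_cols) == 0) {
    abort_format("no 'LFQ intensity <sample>' columns to pivot")
  }
  ids <- tab$`Majority protein IDs`
  if (anyDuplicated(ids)) {
    abort_format(paste0("duplicated majority protein IDs: ",
                        ids[duplicated(ids)][1]))
  }
  long <- tab %>%
    dplyr::select("Majority protein IDs", dplyr::all_of(lfq_cols)) %>%
    tidyr::pivot_longer(dplyr::all_of(lfq_cols), names_to = "sample_id",
                        values_to = "intensity") %>%
    dplyr::mutate(
      protein_id = .data$`Majority protein IDs`,
      sample_id = sub("^LFQ intensity ", "", .data$sample_id),
      condition = sub("_[0-9]+$", "", .data$sample_id),
      observed = !is.na(.data$intensity) & .data$intensity > 0,
      log2_intensity = dplyr::if_else(.data$observed,
                                      log2(.data$intensity), NA_real_),
      imputed = FALSE
    ) %>%
    dplyr::select("protein_id", "sample_id", "condition", "log2_intensity",
                  "observed", "imputed")
  attr(long, "filter_report") <- filter_report(tab)
  long
}

#' Apply the valid-value filter
#'
#' Retains proteins that have at least `min_valid` observed (non-missing,
#' non-imputed) values in at least one condition; all other proteins are
#' dropped. Conditions listed in `exclude` (by default the no-biotin negative
#' control `BC`) do not count towards the rule. The number of proteins failing
#' the rule is recorded in the [filter_report()].
#'
#' @param x A long intensity tibble from [pivot_intensities()].
#' @param min_valid Minimum observed values required in some condition.
#' @param exclude Conditions excluded from the rule.
#' @return The filtered long tibble.
#' @export
valid_value_filter <- function(x, min_valid = 2, exclude = "BC") {
  min_valid <- check_count(min_valid, "min_valid", min = 1)
  eligible <- x %>% dplyr::filter(!.data$condition %in% exclude)
  reps_per_cond <- eligible %>%
    dplyr::distinct(.data$condition, .data$sample_id) %>%
    dplyr::count(.data$condition, name = "n_reps")
  if (nrow(reps_per_cond) > 0 && min_valid > max(reps_per_cond$n_reps)) {
    abort_config(paste0("`min_valid` (", min_valid,
                        ") exceeds the largest replicate count (",
                        max(reps_per_cond$n_reps), ")"))
  }
  keep <- eligible %>%
    dplyr::group_by(.data$protein_id, .data$condition) %>%
    dplyr::summarise(n_obs = sum(.data$observed), .groups = "drop") %>%
    dplyr::group_by(.data$protein_id) %>%
    dplyr::summarise(pass = max(.data$n_obs) >= min_valid, .groups = "drop")
  keep_ids <- keep$protein_id[keep$pass]
  report <- filter_report(x)
  n_before <- dplyr::n_distinct(x$protein_id)
  report$n_failed_valid_filter <- report$n_failed_valid_filter +
    (n_before - length(keep_ids))
  report$n_retained <- length(keep_ids)
  out <- x %>% dplyr::filter(.data$protein_id %in% keep_ids)
  attr(out, "filter_report") <- report
  out
}

#' Impute censored values from a downshifted normal distribution
#'
#' Fills the missing cells of each sample with draws from a normal
#' distribution centred around that sample's detection limit, operationalized
#' per sample as `mean_s - downshift * sd_s` with spread `width * sd_s`, where
#' `mean_s` and `sd_s` are the mean and SD of the sample's observed log2
#' intensities. These are the widely used downshifted-normal defaults
#' (downshift 1.8 SD, width 0.3 SD) for left-censored label-free data.
#' Observed values are never modified; imputed cells are flagged in the
#' `imputed` column. Conditions in `exclude` (the all-missing negative
#' control) are left untouched.
#'
#' @param x A long intensity tibble that passed [valid_value_filter()].
#' @param downshift,width Multiples of the per-sample SD.
#' @param seed Optional seed for reproducible draws.
#' @param exclude Conditions left unimputed.
#' @return The long tibble with missing cells filled and `imputed` updated.
#' @export
impute_missing <- function(x, downshift = 1.8, width = 0.3, seed = NULL,
                           exclude = "BC") {
  check_positive(downshift, "downshift")
  if (!is.numeric(width) || length(width) != 1L || width < 0) {
    abort_config("`width` must be a non-negative number")
  }
  stats_by_sample <- x %>%
    dplyr::filter(!.data$condition %in% exclude) %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      n_obs = sum(.data$observed),
      mean_s = mean(.data$log2_intensity[.data$observed]),
      sd_s = stats::sd(.data$log2_intensity[.data$observed]),
      .groups = "drop"
    )
  too_few <- stats_by_sample$sample_id[stats_by_sample$n_obs < 2]
  if (length(too_few) > 0) {
    abort_imputation(paste0("sample '", too_few[1],
                            "' has fewer than 2 observed values"))
  }
  out <- x %>%
    dplyr::left_join(stats_by_sample, by = "sample_id") %>%
    dplyr::arrange(.data$sample_id, .data$protein_id)
  fill <- !out$observed & !out$condition %in% exclude
  n_fill <- sum(fill)
  draws <- with_local_seed(seed, rnorm(n_fill))
  out$log2_intensity[fill] <- out$mean_s[fill] - downshift * out$sd_s[fill] +
    width * out$sd_s[fill] * draws
  out$imputed[fill] <- TRUE
  out <- out %>% dplyr::select(-"n_obs", -"mean_s", -"sd_s")
  attr(out, "filter_report") <- filter_report(x)
  out
}

#' Ingest a protein-groups file end to end
#'
#' Convenience wrapper chaining [read_protein_groups()],
#' [remove_decoys_and_contaminants()], [pivot_intensities()],
#' [valid_value_filter()] and [impute_missing()].
#'
#' @param path Path to the protein-groups TSV.
#' @param min_valid,downshift,width,seed,exclude Passed to the stages.
#' @return A long intensity tibble ready for testing and detection calls.
#' @export
ingest_protein_groups <- function(path, min_valid = 2, downshift = 1.8,
                                  width = 0.3, seed = NULL, exclude = "BC") {
  read_protein_groups(path) %>%
    remove_decoys_and_contaminants() %>%
    pivot_intensities() %>%
    valid_value_filter(min_valid = min_valid, exclude = exclude) %>%
    impute_missing(downshift = downshift, width = width, seed = seed,
                   exclude = exclude)
}
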