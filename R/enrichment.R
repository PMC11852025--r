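# Generic overrepresentation statistic: fold enrichment plus a two-sided
# Fisher exact test with Bonferroni correction, run for every annotation term
# of a background against a sample subset. The exact p-value is computed
# directly as the hypergeometric sum (all tables as extreme as the observed
# one under fixed margins), which vectorizes over many terms/tables;
# stats::fisher.test matches it and serves as the independent oracle in the
# test suite.

#' Two-sided Fisher exact p-value for 2x2 tables
#'
#' `a` counts sample proteins with the term, `b` sample without, `c`
#' background-only with, `d` background-only without. The two-sided p-value
#' sums the hypergeometric probabilities of all tables (with the same
#' margins) no more probable than the observed one, using the conventional
#' relative tolerance of 1e-7 when comparing probabilities. Vectorized over
#' tables.
#'
#' @param a,b,c,d Non-negative integer cell counts (recycled).
#' @return Numeric vector of p-values.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d)))) {
    abort_value("cell counts must be non-negative integers")
  }
  vapply(seq_len(n), function(i) {
    m <- a[i] + c[i]          # term-annotated
    nn <- b[i] + d[i]         # not annotated
    k <- a[i] + b[i]          # sample size
    lo <- max(0, k - nn)
    hi <- min(k, m)
    supp <- lo:hi
    dens <- stats::dhyper(supp, m, nn, k)
    d_obs <- stats::dhyper(a[i], m, nn, k)
    sum(dens[dens <= d_obs * (1 + 1e-7)])
  }, numeric(1))
}

#' Bonferroni correction
#'
#' Each p-value is multiplied by the number of tests and capped at 1.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param m Number of tests; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort_value("p-values must lie in [0, 1]")
  }
  pmin(1, m * p)
}

#' Overrepresentation test of a protein set against a background
#'
#' For every annotation term present in the background, builds the 2x2 table
#' (sample / not sample x term / not term), computes the fold enrichment
#' `FE = observed / expected` (expected = sample size times the background
#' annotation rate), the two-sided Fisher exact p-value and its Bonferroni
#' correction over the number of terms actually tested. Direction is `over`
#' when the observed count exceeds the expectation, else `under`.
#'
#' @param sample_ids Protein IDs of the sample set (must be a subset of the
#'   background).
#' @param background A long tibble with columns `protein_id` and `term_id`
#'   (one row per annotation).
#' @param alpha Significance level applied when `significant_only = TRUE`.
#' @param significant_only Keep only terms with `p_bonferroni <= alpha`.
#' @return A tibble of class `enrichment_result` with one row per term:
#'   counts, `fold_enrichment`, `p_raw`, `p_bonferroni`, `direction`.
#' @export
overrepresentation <- function(sample_ids, background, alpha = 0.05,
                               significant_only = FALSE) {
  if (!all(c("protein_id", "term_id") %in% names(background))) {
    abort_format("`background` needs columns protein_id and term_id")
  }
  bg_ids <- unique(background$protein_id)
  sample_ids <- unique(sample_ids)
  outsiders <- setdiff(sample_ids, bg_ids)
  if (length(outsiders) > 0) {
    abort_input(paste0("sample proteins absent from the background: ",
                       paste(utils::head(outsiders, 5), collapse = ", ")))
  }
  n_background <- length(bg_ids)
  n_sample <- length(sample_ids)
  per_term <- background %>%
    dplyr::distinct(.data$protein_id, .data$term_id) %>%
    dplyr::group_by(.data$term_id) %>%
    dplyr::summarise(
      n_background_with_term = dplyr::n(),
      n_sample_with_term = sum(.data$protein_id %in% sample_ids),
      .groups = "drop"
    )
  expected <- n_sample * per_term$n_background_with_term / n_background
  a <- per_term$n_sample_with_term
  b <- n_sample - a
  c <- per_term$n_background_with_term - a
  d <- (n_background - n_sample) - c
  out <- per_term %>%
    dplyr::mutate(
      n_background = n_background,
      n_sample = n_sample,
      expected = expected,
      fold_enrichment = dplyr::if_else(expected > 0,
                                       .data$n_sample_with_term / expected,
                                       NA_real_),
      p_raw = fisher_exact_p(a, b, c, d),
      p_bonferroni = bonferroni(.data$p_raw, m = dplyr::n()),
      direction = dplyr::if_else(.data$n_sample_with_term >= expected,
                                 "over", "under")
    ) %>%
    dplyr::arrange(.data$p_raw, .data$term_id)
  if (significant_only) {
    out <- out %>% dplyr::filter(.data$p_bonferroni <= alpha)
  }
  class(out) <- c("enrichment_result", class(out))
  out
}
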