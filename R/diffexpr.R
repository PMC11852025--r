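# Empirical-Bayes moderated two-group testing. The per-protein within-group
# variance is shrunk toward a prior variance estimated across all proteins by
# moment matching on log sample variances; the moderated t gains the prior
# degrees of freedom.

# Inverse of trigamma by Newton iteration on 1/trigamma (monotone, nearly
# linear), as is standard for fitting scaled-F variance distributions.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits a scaled-inverse-chi-square prior `(d0, s0^2)` to per-protein sample
#' variances by moment matching on the log variances: the mean and variance of
#' `log(s^2)` are matched to those implied by the scaled-F marginal
#' distribution of sample variances under the prior. When the empirical
#' spread of `log(s^2)` does not exceed the spread expected from sampling
#' alone, the prior degrees of freedom are infinite (all variances shrink
#' completely to `s0^2`, taken as the mean sample variance).
#'
#' @param variances Per-protein sample variances (at least 10, not all zero).
#' @param df Residual degrees of freedom of each variance (a single value).
#' @return An object of class `variance_prior`: a list with `d0`, `s0_sq`,
#'   `df` and `n`.
#' @export
estimate_variance_prior <- function(variances, df) {
  if (!is.numeric(df) || length(df) != 1L || df < 1) {
    abort_config("`df` must be a single residual degree of freedom >= 1")
  }
  variances <- variances[!is.na(variances)]
  if (all(variances == 0)) {
    abort_degenerate("all sample variances are zero")
  }
  pos <- variances[variances > 0]
  if (length(pos) < 10) {
    abort_config("need at least 10 proteins with positive variance and df >= 1")
  }
  z <- log(pos)
  evar <- stats::var(z) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(pos)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, df = df, n = length(pos)),
            class = "variance_prior")
}

#' Construct a variance prior directly
#'
#' Mostly useful for limiting cases: `d0 = 0` disables moderation (ordinary
#' pooled-variance t), `d0 = Inf` shrinks every protein's variance completely
#' to `s0_sq`.
#'
#' @param d0 Prior degrees of freedom (`>= 0`, may be `Inf`).
#' @param s0_sq Prior variance (`> 0`).
#' @return An object of class `variance_prior`.
#' @export
variance_prior <- function(d0, s0_sq) {
  if (!is.numeric(d0) || length(d0) != 1L || is.na(d0) || d0 < 0) {
    abort_config("`d0` must be a single number >= 0 (possibly Inf)")
  }
  check_positive(s0_sq, "s0_sq")
  structure(list(d0 = d0, s0_sq = s0_sq, df = NA_real_, n = NA_integer_),
            class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat("Variance prior: d0 =", format(x$d0), ", s0^2 =", format(x$s0_sq),
      "(from", x$n, "proteins, residual df", x$df, ")\n")
  invisible(x)
}

#' Moderated two-group t-test for one contrast
#'
#' For every protein, computes the log2 fold change (mean of the first
#' condition minus mean of the second), the pooled within-group variance
#' `s_g^2` with `df_g = n1 + n2 - 2`, the posterior variance
#' `s~^2 = (d0*s0^2 + df_g*s_g^2) / (d0 + df_g)`, and the moderated statistic
#' `t = log2fc / (s~ * sqrt(1/n1 + 1/n2))`, referred to a t distribution with
#' `df_g + d0` degrees of freedom (two-sided). With `d0 = 0` this is the
#' ordinary pooled-variance two-sample t-test; with `d0 = Inf` the variance is
#' fully shrunk to `s0^2` and the reference distribution is normal.
#'
#' Values used are the observed-plus-imputed log2 intensities; pass
#' `observed_only = TRUE` for a sensitivity analysis on observed cells alone
#' (proteins with fewer than two values in either group then get `NA`
#' statistics).
#'
#' @param x A long intensity tibble (normally after [impute_missing()]).
#' @param contrast Character pair of condition labels, first minus second.
#' @param prior A [estimate_variance_prior()] object, or `NULL` to estimate it
#'   from this contrast's pooled variances.
#' @param observed_only Use only observed (never imputed) values.
#' @return A tibble of class `surfmark_contrast` with columns `protein_id`,
#'   `contrast`, `log2fc`, `t_mod`, `df_total`, `p_raw`; the prior is attached
#'   as attribute `prior`.
#' @export
moderated_ttest <- function(x, contrast, prior = NULL, observed_only = FALSE) {
  if (length(contrast) != 2L) {
    abort_contrast("`contrast` must be a pair of condition labels")
  }
  missing_cond <- setdiff(contrast, unique(x$condition))
  if (length(missing_cond) > 0) {
    abort_contrast(paste0("unknown condition label '", missing_cond[1], "'"))
  }
  vals <- x %>% dplyr::filter(.data$condition %in% contrast)
  if (observed_only) {
    vals <- vals %>% dplyr::filter(.data$observed)
  } else {
    vals <- vals %>% dplyr::filter(.data$observed | .data$imputed)
  }
  per_group <- vals %>%
    dplyr::group_by(.data$protein_id, .data$condition) %>%
    dplyr::summarise(
      n = sum(is.finite(.data$log2_intensity)),
      m = mean(.data$log2_intensity),
      v = stats::var(.data$log2_intensity),
      .groups = "drop"
    )
  wide <- per_group %>%
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("n", "m", "v"))
  n1 <- wide[[paste0("n_", contrast[1])]] %||% rep(0L, nrow(wide))
  n2 <- wide[[paste0("n_", contrast[2])]] %||% rep(0L, nrow(wide))
  m1 <- wide[[paste0("m_", contrast[1])]]
  m2 <- wide[[paste0("m_", contrast[2])]]
  v1 <- wide[[paste0("v_", contrast[1])]]
  v2 <- wide[[paste0("v_", contrast[2])]]
  n1[is.na(n1)] <- 0L; n2[is.na(n2)] <- 0L
  ok <- n1 >= 2 & n2 >= 2
  df_g <- ifelse(ok, n1 + n2 - 2, NA_real_)
  s2_g <- ifelse(ok, ((n1 - 1) * v1 + (n2 - 1) * v2) / df_g, NA_real_)
  log2fc <- m1 - m2

  if (is.null(prior)) {
    prior <- estimate_variance_prior(s2_g[ok], df = stats::median(df_g[ok]))
  }
  d0 <- prior$d0
  s0_sq <- prior$s0_sq
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2_g))
    s2_post[!ok] <- NA_real_
    df_total <- rep(Inf, length(s2_g))
  } else {
    s2_post <- (d0 * s0_sq + df_g * s2_g) / (d0 + df_g)
    df_total <- df_g + d0
  }
  t_mod <- log2fc / sqrt(s2_post * (1 / n1 + 1 / n2))
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)

  out <- tibble::tibble(
    protein_id = wide$protein_id,
    contrast = paste(contrast, collapse = "-"),
    log2fc = log2fc,
    t_mod = t_mod,
    df_total = df_total,
    p_raw = p_raw
  )
  attr(out, "prior") <- prior
  class(out) <- c("surfmark_contrast", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. For a numeric vector, returns the
#' adjusted p-values; for a contrast result, adds a `p_adj` column (adjusted
#' within each contrast).
#'
#' @param x Numeric p-values in `[0, 1]`, or a [moderated_ttest()] result.
#' @param ... Unused.
#' @return Adjusted p-values, or the tibble with `p_adj` added.
#' @export
adjust_bh <- function(x, ...) UseMethod("adjust_bh")

#' @export
adjust_bh.default <- function(x, ...) {
  p <- x[!is.na(x)]
  if (any(p < 0 | p > 1)) {
    abort_value("p-values must lie in [0, 1]")
  }
  stats::p.adjust(x, method = "BH")
}

#' @export
adjust_bh.data.frame <- function(x, ...) {
  if (!"p_raw" %in% names(x)) {
    abort_value("expected a `p_raw` column")
  }
  old_attrs <- attributes(x)
  out <- x %>%
    dplyr::group_by(.data$contrast) %>%
    dplyr::mutate(p_adj = adjust_bh(.data$p_raw)) %>%
    dplyr::ungroup()
  attr(out, "prior") <- old_attrs$prior
  class(out) <- old_attrs$class
  out
}

#' Call differential regulation
#'
#' Applies the study's significance rule: a protein is significantly
#' regulated in a contrast when its BH-adjusted p-value is strictly below
#' `alpha` and its absolute log2 fold change is at least `lfc_threshold`
#' (default FDR < 0.05 and |log2FC| >= 2). The direction is `up`/`down` in
#' the contrast's first condition.
#'
#' @param x A contrast result carrying `p_adj` (see [adjust_bh()]).
#' @param alpha FDR threshold (strict `<`).
#' @param lfc_threshold Minimum absolute log2 fold change (`>=`).
#' @return The tibble with `significant` and `direction` columns added.
#' @export
call_regulation <- function(x, alpha = 0.05, lfc_threshold = 2) {
  if (!"p_adj" %in% names(x)) {
    abort_value("`p_adj` missing: run adjust_bh() first")
  }
  old_attrs <- attributes(x)
  out <- x %>%
    dplyr::mutate(
      significant = !is.na(.data$p_adj) & .data$p_adj < alpha &
        abs(.data$log2fc) >= lfc_threshold,
      direction = dplyr::if_else(.data$log2fc >= 0, "up", "down")
    )
  attr(out, "prior") <- old_attrs$prior
  class(out) <- old_attrs$class
  out
}

#' Run all contrasts of the study design
#'
#' Tests each condition pair (by default BU-BX, BU-BY and BX-BY) with the
#' moderated t-test, applies BH adjustment within each contrast and the
#' significance rule, and binds the results.
#'
#' @param x A long intensity tibble after imputation.
#' @param contrasts List of condition pairs.
#' @param alpha,lfc_threshold Passed to [call_regulation()].
#' @param prior Optional shared [estimate_variance_prior()] object; by default
#'   each contrast estimates its own prior from its pooled variances.
#' @param observed_only Passed to [moderated_ttest()].
#' @return A `surfmark_contrast` tibble over all contrasts.
#' @export
run_diffexpr <- function(x,
                         contrasts = list(c("BU", "BX"), c("BU", "BY"),
                                          c("BX", "BY")),
                         alpha = 0.05, lfc_threshold = 2, prior = NULL,
                         observed_only = FALSE) {
  res <- purrr::map(contrasts, function(ct) {
    moderated_ttest(x, ct, prior = prior, observed_only = observed_only) %>%
      adjust_bh() %>%
      call_regulation(alpha = alpha, lfc_threshold = lfc_threshold)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "prior") <- attr(res[[1]], "prior")
  class(out) <- c("surfmark_contrast", class(tibble::tibble()))
  out
}
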