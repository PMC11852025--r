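# broom-style accessors for the pipeline's result objects.

#' @describeIn moderated_ttest Tidy per-protein contrast results (plain
#'   tibble, one row per protein and contrast).
#' @param x,... Method arguments.
#' @export
tidy.surfmark_contrast <- function(x, ...) {
  out <- x
  attr(out, "prior") <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' @describeIn moderated_ttest One row per contrast: number tested,
#'   significant, up/down counts, and the variance-prior parameters.
#' @export
glance.surfmark_contrast <- function(x, ...) {
  prior <- attr(x, "prior")
  out <- tidy(x) %>%
    dplyr::group_by(.data$contrast) %>%
    dplyr::summarise(
      n_proteins = dplyr::n(),
      n_significant = if ("significant" %in% names(x)) {
        sum(.data$significant, na.rm = TRUE)
      } else NA_integer_,
      n_up = if ("significant" %in% names(x)) {
        sum(.data$significant & .data$direction == "up", na.rm = TRUE)
      } else NA_integer_,
      n_down = if ("significant" %in% names(x)) {
        sum(.data$significant & .data$direction == "down", na.rm = TRUE)
      } else NA_integer_,
      .groups = "drop"
    )
  if (!is.null(prior)) {
    out$prior_d0 <- prior$d0
    out$prior_s0_sq <- prior$s0_sq
  }
  out
}

#' @describeIn estimate_variance_prior Tidy the prior as a one-row tibble.
#' @param x,... Method arguments.
#' @export
tidy.variance_prior <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq, df = x$df, n = x$n)
}

#' @describeIn call_targets Tidy target calls: evidence flattened to a
#'   `;`-separated string.
#' @param x,... Method arguments.
#' @export
tidy.target_calls <- function(x, ...) {
  out <- x %>%
    dplyr::mutate(
      evidence = vapply(.data$evidence, paste, character(1), collapse = ";"),
      tier = as.character(.data$tier)
    )
  class(out) <- class(tibble::tibble())
  out
}

#' @describeIn call_targets One-row summary: tier counts.
#' @export
glance.target_calls <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_accessible = sum(x$tier >= "accessible"),
    n_prioritized = sum(x$tier == "prioritized"),
    n_transmembrane = sum(x$is_transmembrane)
  )
}
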