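# Internal helpers shared across modules.

surfmark_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "surfmark_error"))
}

abort_config <- function(message) surfmark_abort(message, "surfmark_config_error")
abort_format <- function(message) surfmark_abort(message, "surfmark_format_error")
abort_value <- function(message) surfmark_abort(message, "surfmark_value_error")
abort_input <- function(message) surfmark_abort(message, "surfmark_input_error")
abort_join <- function(message) surfmark_abort(message, "surfmark_join_error")
abort_validation <- function(message) surfmark_abort(message, "surfmark_validation_error")
abort_imputation <- function(message) surfmark_abort(message, "surfmark_imputation_error")
abort_contrast <- function(message) surfmark_abort(message, "surfmark_contrast_error")
abort_degenerate <- function(message) surfmark_abort(message, "surfmark_degenerate_error")

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_config("`seed` must be a single finite number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_config(paste0("`", name, "` must be a proportion in [0, 1]"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort_config(paste0("`", name, "` must be an integer >= ", min))
  }
  invisible(as.integer(x))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort_config(paste0("`", name, "` must be a positive number"))
  }
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
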