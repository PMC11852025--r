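# The candidate-selection rule engine: join detection, GO-interest and
# topology evidence into surface-accessibility calls and candidate tiers.

#' Surface accessibility of annotated proteins
#'
#' Joins interest calls with topology records and applies the accessibility
#' disjunction: a protein is possibly accessible from the cell surface when
#' (1) it hits any of the categories `CS`, `ESPM`, `ECESPM`, `ACESPM`,
#' `ICESPM`, `ESCW`, `ESCOM`; or (2) it hits `PM`, `ACPM` or `ICPM` and is
#' transmembrane or has part of its sequence predicted outside the cell
#' membrane; or (3) it hits `ES` and is transmembrane. Proteins missing from
#' the topology records are treated as globular with unknown (hence no)
#' outside region, with a warning; a protein whose only evidence is `ES` with
#' unknown topology is therefore not accessible (conservative).
#'
#' @param interest A [classify_interest()] tibble.
#' @param topo Topology records (see [parse_3line()]), joined on the interest
#'   table's `unique_protein_id` if present, else `protein_id`.
#' @return The interest tibble with `is_transmembrane`,
#'   `has_outside_region`, resolved `of_interest` and `surface_accessible`
#'   columns added.
#' @export
surface_accessible <- function(interest, topo) {
  key <- if ("unique_protein_id" %in% names(interest)) {
    interest$unique_protein_id
  } else {
    interest$protein_id
  }
  idx <- match(key, topo$protein_id)
  if (anyNA(idx)) {
    rlang::warn(paste0(sum(is.na(idx)),
                       " protein(s) without topology treated as globular-unknown"))
  }
  is_tm <- ifelse(is.na(idx), FALSE, is_transmembrane(topo)[idx])
  has_out <- ifelse(is.na(idx), FALSE, topo$has_outside_region[idx])
  topo_class <- ifelse(is.na(idx), NA_character_, topo$predicted_class[idx])

  always <- vapply(interest$categories, function(cc) {
    any(cc %in% GO_CATEGORIES_ACCESS_ALWAYS)
  }, logical(1))
  pm_group <- vapply(interest$categories, function(cc) {
    any(cc %in% GO_CATEGORIES_ACCESS_PM)
  }, logical(1))
  has_es <- vapply(interest$categories, function(cc) "ES" %in% cc, logical(1))

  out <- interest
  out$topology_class <- topo_class
  out$is_transmembrane <- is_tm
  out$has_outside_region <- has_out
  out$of_interest <- out$of_interest | (has_es & is_tm)
  out$surface_accessible <- always |
    (pm_group & (is_tm | has_out)) |
    (has_es & is_tm)
  out
}

#' Call candidate tiers
#'
#' The prioritization rule: a protein reaches tier `accessible` when it is
#' surface-accessible, detected in at least one replicate of the target
#' condition (BX by default) and in zero replicates of the opposite sexed
#' condition (BY); it reaches tier `prioritized` when it is additionally
#' transmembrane and detected in at least `min_bx_reps` target replicates.
#' The engine is symmetric: `direction = "BY"` swaps the roles of BX and BY
#' for datasets with Y-specific candidates.
#'
#' @param profiles A [detection_profiles()] tibble.
#' @param interest A [classify_interest()] tibble.
#' @param topo Topology records.
#' @param min_bx_reps Replicate threshold for prioritization.
#' @param direction Target condition, `"BX"` or `"BY"`.
#' @return A tibble of class `target_calls`: `protein_id`, `of_interest`,
#'   `surface_accessible`, `bx_replicates_detected`,
#'   `by_replicates_detected`, `is_transmembrane`, `tier` (ordered factor
#'   `none < accessible < prioritized`) and an `evidence` list-column naming
#'   every satisfied rule.
#' @export
call_targets <- function(profiles, interest, topo, min_bx_reps = 2,
                         direction = c("BX", "BY")) {
  direction <- match.arg(direction)
  target_cond <- direction
  off_cond <- if (direction == "BX") "BY" else "BX"
  min_bx_reps <- check_count(min_bx_reps, "min_bx_reps", min = 1)

  acc <- surface_accessible(interest, topo)
  wide <- profiles_wide(profiles, c(target_cond, off_cond))
  for (cn in c(target_cond, off_cond)) {
    if (is.null(wide[[cn]])) wide[[cn]] <- 0L
  }
  idx <- match(acc$protein_id, wide$protein_id)
  n_target <- ifelse(is.na(idx), 0L, wide[[target_cond]][idx])
  n_off <- ifelse(is.na(idx), 0L, wide[[off_cond]][idx])

  accessible <- acc$surface_accessible & n_target >= 1L & n_off == 0L
  prioritized <- accessible & n_target >= min_bx_reps & acc$is_transmembrane
  tier <- factor(
    dplyr::case_when(prioritized ~ "prioritized",
                     accessible ~ "accessible",
                     TRUE ~ "none"),
    levels = c("none", "accessible", "prioritized"), ordered = TRUE
  )

  evidence <- purrr::pmap(
    list(acc$categories, acc$topology_class, acc$is_transmembrane,
         acc$has_outside_region, n_target, n_off),
    function(cc, cls, tm, outr, nt, no) {
      c(
        paste0("go:", cc),
        if (!is.na(cls)) paste0("topology:", cls),
        if (tm) "transmembrane",
        if (outr) "outside-region",
        paste0(tolower(target_cond), "_reps:", nt),
        if (no == 0L) paste0("absent_in_", off_cond)
      )
    }
  )

  out <- tibble::tibble(
    protein_id = acc$protein_id,
    of_interest = acc$of_interest,
    surface_accessible = acc$surface_accessible,
    bx_replicates_detected = as.integer(n_target),
    by_replicates_detected = as.integer(n_off),
    is_transmembrane = acc$is_transmembrane,
    tier = tier,
    evidence = evidence
  )
  class(out) <- c("target_calls", class(out))
  out
}

#' Tabular candidate report
#'
#' Joins target calls with annotation (gene name and chromosome), sorts by
#' tier (prioritized first) then gene name, and flags X-linked candidates.
#' Chromosome strings are reported verbatim.
#'
#' @param calls A [call_targets()] tibble.
#' @param annotations An [annotate_proteins()] tibble.
#' @return A tibble sorted by tier then gene name, with an `x_linked` flag.
#' @export
selection_report <- function(calls, annotations) {
  ann <- annotations %>%
    dplyr::select(dplyr::any_of(c("protein_id", "unique_protein_id", "gene",
                                  "chromosome")))
  out <- calls %>%
    dplyr::select(-"evidence") %>%
    dplyr::left_join(ann, by = "protein_id") %>%
    dplyr::mutate(x_linked = !is.na(.data$chromosome) &
                    .data$chromosome == "X") %>%
    dplyr::arrange(dplyr::desc(.data$tier), .data$gene, .data$protein_id)
  out
}
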