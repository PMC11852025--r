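# Per-condition detection calls and set partitions. Detection always uses
# observed cells only, never imputed ones.

#' Per-condition detection profiles
#'
#' Counts, for every protein and condition, in how many replicates the protein
#' was observed (a measured, non-imputed LFQ value). "Identified" is
#' operationalized as "has an observed LFQ value" since the pipeline works
#' from the quantification table.
#'
#' @param x A long intensity tibble.
#' @return A tibble of class `detection_profiles` with columns `protein_id`,
#'   `condition`, `n_replicates`, `n_detected`, `detected`.
#' @export
detection_profiles <- function(x) {
  reps <- x %>%
    dplyr::distinct(.data$condition, .data$sample_id) %>%
    dplyr::count(.data$condition, name = "n_replicates")
  out <- x %>%
    dplyr::group_by(.data$protein_id, .data$condition) %>%
    dplyr::summarise(n_detected = sum(.data$observed), .groups = "drop") %>%
    dplyr::left_join(reps, by = "condition") %>%
    dplyr::mutate(detected = .data$n_detected >= 1L) %>%
    dplyr::select("protein_id", "condition", "n_replicates", "n_detected",
                  "detected")
  class(out) <- c("detection_profiles", class(out))
  out
}

profiles_wide <- function(profiles, sets) {
  profiles %>%
    dplyr::filter(.data$condition %in% sets) %>%
    dplyr::select("protein_id", "condition", "n_detected") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "n_detected",
                       values_fill = 0L)
}

#' Venn partition of detection calls
#'
#' Partitions the retained proteins into the regions of the detection Venn
#' diagram over the given conditions (all seven non-empty intersections for
#' three sets, plus the proteins detected in none). Regions are disjoint and
#' sum to the total.
#'
#' @param profiles A [detection_profiles()] tibble.
#' @param sets Conditions forming the diagram.
#' @return A tibble with columns `region` and `n`.
#' @export
venn_partition <- function(profiles, sets = c("BU", "BX", "BY")) {
  wide <- profiles_wide(profiles, sets)
  flags <- as.data.frame(lapply(sets, function(s) wide[[s]] >= 1L))
  names(flags) <- sets
  region <- apply(flags, 1L, function(f) {
    if (!any(f)) "none" else paste(sets[f], collapse = "&")
  })
  all_regions <- c(
    unlist(lapply(seq_along(sets), function(k) {
      apply(utils::combn(sets, k), 2L, paste, collapse = "&")
    })),
    "none"
  )
  counts <- table(factor(region, levels = all_regions))
  tibble::tibble(region = all_regions, n = as.integer(counts))
}

#' Exclusive and absence detection sets
#'
#' Classifies each protein by its detection pattern across BU, BX and BY:
#' detected exclusively in BX (`bx_only`), exclusively in BU (`bu_only`), in
#' both BX and BU but not BY (`bx_and_bu`), and the absence sets
#' `absent_in_BY` (detected in BX or BU, zero BY replicates) and
#' `absent_in_BX` (detected in BU or BY, zero BX replicates).
#'
#' @param profiles A [detection_profiles()] tibble.
#' @return A tibble with `protein_id` and one logical column per set.
#' @export
exclusive_sets <- function(profiles) {
  wide <- profiles_wide(profiles, c("BU", "BX", "BY"))
  for (cn in c("BU", "BX", "BY")) {
    if (is.null(wide[[cn]])) wide[[cn]] <- 0L
  }
  wide %>%
    dplyr::mutate(
      bu = .data$BU >= 1L, bx = .data$BX >= 1L, by = .data$BY >= 1L,
      bx_only = .data$bx & !.data$bu & !.data$by,
      bu_only = .data$bu & !.data$bx & !.data$by,
      bx_and_bu = .data$bx & .data$bu & !.data$by,
      absent_in_BY = (.data$bx | .data$bu) & !.data$by,
      absent_in_BX = (.data$bu | .data$by) & !.data$bx
    ) %>%
    dplyr::select("protein_id", "bx_only", "bu_only", "bx_and_bu",
                  "absent_in_BY", "absent_in_BX")
}

#' Build the heatmap set
#'
#' Collects the proteins to display: those significantly regulated in any
#' contrast, plus those completely absent in BX or in BY. Their log2 LFQ
#' intensities (observed plus imputed; the all-missing negative control is
#' excluded) are z-scored per protein and ordered by agglomerative
#' hierarchical clustering (Euclidean distance, average linkage); the row
#' order is the dendrogram's leaf order, deterministic given the input order.
#' Members with fewer than two finite values are excluded with a warning.
#'
#' @param x A long intensity tibble after imputation.
#' @param results A [run_diffexpr()] result with `significant` calls.
#' @param profiles A [detection_profiles()] tibble.
#' @param exclude Conditions dropped from the display (negative control).
#' @return An object of class `heatmap_set`: a list with `members` (tibble of
#'   `protein_id` and a `reasons` list-column), `z` (long tibble of z-scores
#'   with an `observed` flag; missing non-imputed cells are `NA`, the gray
#'   sentinel in exports), and `row_order` (protein IDs in dendrogram order).
#' @export
build_heatmap_set <- function(x, results, profiles, exclude = "BC") {
  sig_ids <- unique(results$protein_id[results$significant %||% FALSE])
  sets <- exclusive_sets(profiles)
  absent_bx <- sets$protein_id[sets$absent_in_BX]
  absent_by <- sets$protein_id[sets$absent_in_BY]
  members <- tibble::tibble(protein_id = unique(c(sig_ids, absent_bx, absent_by)))
  members$reasons <- lapply(members$protein_id, function(p) {
    c(if (p %in% sig_ids) "significant-in-a-contrast",
      if (p %in% absent_bx) "absent-in-BX",
      if (p %in% absent_by) "absent-in-BY")
  })
  if (nrow(members) == 0L) {
    return(structure(list(members = members,
                          z = tibble::tibble(protein_id = character(0),
                                             sample_id = character(0),
                                             z = numeric(0),
                                             observed = logical(0)),
                          row_order = character(0)),
                     class = "heatmap_set"))
  }
  vals <- x %>%
    dplyr::filter(.data$protein_id %in% members$protein_id,
                  !.data$condition %in% exclude) %>%
    dplyr::mutate(value = dplyr::if_else(.data$observed | .data$imputed,
                                         .data$log2_intensity, NA_real_))
  z <- vals %>%
    dplyr::group_by(.data$protein_id) %>%
    dplyr::mutate(
      n_finite = sum(is.finite(.data$value)),
      row_sd = stats::sd(.data$value[is.finite(.data$value)]),
      z = dplyr::if_else(
        rep(dplyr::first(.data$row_sd) > 0, dplyr::n()),
        (.data$value - mean(.data$value[is.finite(.data$value)])) /
          .data$row_sd,
        0
      )
    ) %>%
    dplyr::ungroup()
  too_few <- unique(z$protein_id[z$n_finite < 2])
  if (length(too_few) > 0) {
    rlang::warn(paste0(length(too_few),
                       " heatmap member(s) with < 2 finite values excluded"))
    z <- z %>% dplyr::filter(!.data$protein_id %in% too_few)
    members <- members %>% dplyr::filter(!.data$protein_id %in% too_few)
  }
  z <- z %>% dplyr::select("protein_id", "sample_id", "z", "observed")
  zmat <- z %>%
    tidyr::pivot_wider(id_cols = "protein_id", names_from = "sample_id",
                       values_from = "z") %>%
    as.data.frame()
  rownames(zmat) <- zmat$protein_id
  zmat$protein_id <- NULL
  zmat <- as.matrix(zmat)
  zmat[!is.finite(zmat)] <- 0  # distance on the shown values; NA cells neutral
  row_order <- rownames(zmat)
  if (nrow(zmat) > 2) {
    hc <- stats::hclust(stats::dist(zmat), method = "average")
    row_order <- rownames(zmat)[hc$order]
  } else if (nrow(zmat) == 2) {
    row_order <- rownames(zmat)
  }
  structure(list(members = members, z = z, row_order = row_order),
            class = "heatmap_set")
}

#' @export
print.heatmap_set <- function(x, ...) {
  cat("Heatmap set:", nrow(x$members), "proteins\n")
  invisible(x)
}
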