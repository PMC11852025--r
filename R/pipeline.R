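# End-to-end driver: ingest -> differential testing -> detection ->
# annotation + topology -> target selection, with a reproducibility manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage parameter at its
#' default: valid-value filter `min_valid = 2`, downshifted-normal imputation
#' (`downshift = 1.8`, `width = 0.3`), significance at FDR < 0.05 with
#' |log2FC| >= 2, prioritization at `min_bx_reps = 2` in direction BX, and
#' the standard three contrasts. Input paths are `NULL` placeholders.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    protein_groups = NULL,
    uniprot = NULL,
    eggnog = NULL,
    topology = NULL,
    topology_format = "3line",
    out_dir = NULL,
    min_valid = 2,
    downshift = 1.8,
    width = 0.3,
    alpha = 0.05,
    lfc_threshold = 2,
    min_bx_reps = 2,
    direction = "BX",
    control = "BC",
    contrasts = list(c("BU", "BX"), c("BU", "BY"), c("BX", "BY")),
    seed = 1L
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (!is.null(config$contrasts)) {
      config$contrasts <- lapply(config$contrasts, as.character)
    }
  }
  if (!is.list(config)) {
    abort_config("`config` must be a list or a YAML file path")
  }
  cfg <- utils::modifyList(default_config(), config)
  for (f in c("protein_groups", "uniprot", "eggnog", "topology")) {
    if (is.null(cfg[[f]])) {
      abort_config(paste0("config field `", f, "` (input path) is required"))
    }
    if (!file.exists(cfg[[f]])) {
      abort_input(paste0("input file not found: ", cfg[[f]]))
    }
  }
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
                 class = c("surfmark_stage_error", "surfmark_error"),
                 parent = e)
  })
}

#' Run the full marker-discovery pipeline
#'
#' Executes all stages in order on a protein-groups table plus annotation and
#' topology inputs, and (optionally) writes every stage output and a run
#' manifest recording the effective parameters and input checksums. Reruns
#' with the same configuration and inputs reproduce identical outputs.
#'
#' @param config A configuration list (see [default_config()]) or the path to
#'   a YAML file with the same fields.
#' @return Invisibly, a list with elements `matrix` (imputed long intensity
#'   tibble), `filter_report`, `results` (contrast tibble), `profiles`,
#'   `venn`, `sets`, `heatmap`, `annotation`, `topology`, `calls`, `report`
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)

  mat <- run_stage("ingest", ingest_protein_groups(
    cfg$protein_groups, min_valid = cfg$min_valid, downshift = cfg$downshift,
    width = cfg$width, seed = cfg$seed, exclude = cfg$control
  ))
  freport <- filter_report(mat)

  results <- run_stage("diffexpr", run_diffexpr(
    mat, contrasts = cfg$contrasts, alpha = cfg$alpha,
    lfc_threshold = cfg$lfc_threshold
  ))

  profiles <- run_stage("detection", detection_profiles(mat))
  venn <- run_stage("detection", venn_partition(profiles))
  sets <- run_stage("detection", exclusive_sets(profiles))
  heatmap <- run_stage("detection",
                       build_heatmap_set(mat, results, profiles,
                                         exclude = cfg$control))

  annotation <- run_stage("annotation", {
    uniprot <- read_uniprot_annotation(cfg$uniprot)
    eggnog <- read_eggnog_annotation(cfg$eggnog)
    annotate_proteins(unique(mat$protein_id), uniprot, eggnog) %>%
      classify_interest()
  })
  topology <- run_stage("topology", {
    if (identical(cfg$topology_format, "3line")) {
      parse_3line(cfg$topology)
    } else {
      parse_topology_table(cfg$topology)
    }
  })

  calls <- run_stage("targetselect", suppressWarnings(call_targets(
    profiles, annotation, topology, min_bx_reps = cfg$min_bx_reps,
    direction = cfg$direction
  )))
  report <- run_stage("targetselect", selection_report(calls, annotation))

  manifest <- list(
    package_version = as.character(utils::packageVersion("surfmark")),
    parameters = cfg[c("min_valid", "downshift", "width", "alpha",
                       "lfc_threshold", "min_bx_reps", "direction",
                       "control", "seed", "topology_format")],
    contrasts = vapply(cfg$contrasts, paste, character(1), collapse = "-"),
    inputs = lapply(
      setNames(c("protein_groups", "uniprot", "eggnog", "topology"),
               c("protein_groups", "uniprot", "eggnog", "topology")),
      function(f) list(path = cfg[[f]],
                       md5 = unname(tools::md5sum(cfg[[f]])))
    ),
    counts = list(
      retained_proteins = freport$n_retained,
      significant_per_contrast = as.list(
        tapply(results$significant, results$contrast, sum)
      ),
      tiers = as.list(table(calls$tier))
    )
  )

  out <- list(matrix = mat, filter_report = freport, results = results,
              profiles = profiles, venn = venn, sets = sets,
              heatmap = heatmap, annotation = annotation,
              topology = topology, calls = calls, report = report,
              manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    write_pipeline_outputs(out, cfg$out_dir)
  }
  invisible(out)
}

write_pipeline_outputs <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(out$matrix, file.path(dir, "processed_matrix.tsv"))
  jsonlite::write_json(out$filter_report, file.path(dir, "filter_report.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  readr::write_tsv(tidy(out$results), file.path(dir, "contrast_results.tsv"))
  jsonlite::write_json(out$venn, file.path(dir, "venn_counts.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  readr::write_tsv(out$sets, file.path(dir, "detection_sets.tsv"))
  readr::write_tsv(out$heatmap$z, file.path(dir, "heatmap_matrix.tsv"))
  writeLines(out$heatmap$row_order, file.path(dir, "heatmap_row_order.txt"))
  ann <- out$annotation %>%
    dplyr::mutate(go_union = vapply(.data$go_union, paste, character(1),
                                    collapse = ";"),
                  categories = vapply(.data$categories, paste, character(1),
                                      collapse = ";")) %>%
    dplyr::select("protein_id", "unique_protein_id", "reviewed", "gene",
                  "chromosome", "go_union", "categories", "of_interest",
                  "interest_es_pending")
  readr::write_tsv(ann, file.path(dir, "annotation.tsv"))
  topo <- out$topology %>%
    dplyr::select("protein_id", "predicted_class", "tmr_count",
                  "has_signal_peptide", "has_outside_region", "length")
  readr::write_tsv(topo, file.path(dir, "topology.tsv"))
  calls <- out$calls %>%
    dplyr::mutate(evidence = vapply(.data$evidence, paste, character(1),
                                    collapse = ";"),
                  tier = as.character(.data$tier))
  readr::write_tsv(calls, file.path(dir, "target_calls.tsv"))
  readr::write_tsv(
    out$report %>% dplyr::mutate(tier = as.character(.data$tier)),
    file.path(dir, "selection_report.tsv")
  )
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
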