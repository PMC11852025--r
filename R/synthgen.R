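#' Configuration for the synthetic surface-proteome generator
#'
#' Builds a validated configuration for [simulate_dataset()]. Defaults emulate
#' the study design the downstream analysis assumes: four conditions (a
#' no-biotin negative control `BC`, unsexed `BU`, X-sorted `BX` and Y-sorted
#' `BY` bovine sperm) with three replicates each, log-normal LFQ intensities,
#' intensity-dependent (detection-limit) missingness, contaminant and
#' reverse-decoy rows, and a set of planted X-sperm-specific proteins of which
#' a subset carry transmembrane topology and a cell-surface GO annotation.
#'
#' @param n_proteins Number of genuine (non-decoy, non-contaminant) proteins.
#' @param conditions Named integer vector of replicate counts per condition,
#'   in column order. The negative control condition (see `control`) is
#'   emitted with all intensities missing.
#' @param control Name of the no-biotin negative-control condition.
#' @param frac_contaminant,frac_reverse Proportions (of `n_proteins`) of
#'   contaminant and reverse-decoy rows appended to the table.
#' @param n_bx_specific Number of planted X-specific proteins: present in BU
#'   and BX at elevated BX abundance, absent by construction in BY.
#' @param n_bx_specific_tm_surface How many of the planted proteins are also
#'   transmembrane with a surface GO term of interest (the recoverable
#'   marker candidates). Must not exceed `n_bx_specific`.
#' @param base_log2_mean Grand mean of protein log2 intensities.
#' @param between_protein_sd Between-protein SD of the log2 means.
#' @param within_group_sd_prior Named pair `c(d0 = , s0 = )`: prior degrees of
#'   freedom and prior SD of the scaled-inverse-chi-square distribution from
#'   which each protein's within-group variance is drawn.
#' @param effect_log2fc Log2 fold change added to the BX group mean of
#'   planted proteins.
#' @param detection_limit Log2 intensity at which the censoring probability is
#'   one half.
#' @param censor_softness Logistic width (log2 units) of the censoring curve;
#'   `0` gives a hard threshold at `detection_limit`.
#' @param mcar_rate Additional missing-completely-at-random rate.
#' @param go_leak_rate Probability that a background protein leaks one GO term
#'   of interest into its annotation (exercises specificity downstream).
#' @param multi_id_rate Fraction of background protein groups carrying two
#'   majority protein IDs (exercises unique-ID selection).
#' @param seed RNG seed; identical configurations produce byte-identical
#'   output files.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_proteins = 50, seed = 1)
#' cfg$n_proteins
sim_config <- function(n_proteins = 500,
                       conditions = c(BC = 3L, BU = 3L, BX = 3L, BY = 3L),
                       control = "BC",
                       frac_contaminant = 0.04,
                       frac_reverse = 0.04,
                       n_bx_specific = 20,
                       n_bx_specific_tm_surface = 5,
                       base_log2_mean = 25,
                       between_protein_sd = 2,
                       within_group_sd_prior = c(d0 = 4, s0 = 0.5),
                       effect_log2fc = 4,
                       detection_limit = 22,
                       censor_softness = 1,
                       mcar_rate = 0,
                       go_leak_rate = 0.05,
                       multi_id_rate = 0.1,
                       seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins")
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    abort_config("`conditions` must be a named vector of replicate counts")
  }
  if (any(conditions < 2)) {
    abort_config("`conditions`: every replicate count must be >= 2")
  }
  if (!control %in% names(conditions)) {
    abort_config("`control` must name one of the `conditions`")
  }
  check_probability(frac_contaminant, "frac_contaminant")
  check_probability(frac_reverse, "frac_reverse")
  check_probability(mcar_rate, "mcar_rate")
  check_probability(go_leak_rate, "go_leak_rate")
  check_probability(multi_id_rate, "multi_id_rate")
  n_bx_specific <- check_count(n_bx_specific, "n_bx_specific")
  n_bx_specific_tm_surface <- check_count(
    n_bx_specific_tm_surface, "n_bx_specific_tm_surface"
  )
  if (n_bx_specific > n_proteins) {
    abort_config("`n_bx_specific` must not exceed `n_proteins`")
  }
  if (n_bx_specific_tm_surface > n_bx_specific) {
    abort_config("`n_bx_specific_tm_surface` must not exceed `n_bx_specific`")
  }
  if (length(within_group_sd_prior) != 2L ||
      !all(c("d0", "s0") %in% names(within_group_sd_prior))) {
    abort_config("`within_group_sd_prior` must be a named pair c(d0 = , s0 = )")
  }
  check_positive(within_group_sd_prior[["d0"]], "within_group_sd_prior['d0']")
  check_positive(within_group_sd_prior[["s0"]], "within_group_sd_prior['s0']")
  check_positive(between_protein_sd, "between_protein_sd")
  if (!is.numeric(censor_softness) || censor_softness < 0) {
    abort_config("`censor_softness` must be a non-negative number")
  }
  structure(
    list(
      n_proteins = n_proteins,
      conditions = setNames(as.integer(conditions), names(conditions)),
      control = control,
      frac_contaminant = frac_contaminant,
      frac_reverse = frac_reverse,
      n_bx_specific = n_bx_specific,
      n_bx_specific_tm_surface = n_bx_specific_tm_surface,
      base_log2_mean = base_log2_mean,
      between_protein_sd = between_protein_sd,
      within_group_sd_prior = within_group_sd_prior,
      effect_log2fc = effect_log2fc,
      detection_limit = detection_limit,
      censor_softness = censor_softness,
      mcar_rate = mcar_rate,
      go_leak_rate = go_leak_rate,
      multi_id_rate = multi_id_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Sample topology classes and build per-residue topology strings.
# Segments alternate sides around each membrane run, so any protein with at
# least one transmembrane region also has at least one outside segment.
simulate_topology_string <- function(class) {
  seg <- character(0)
  signal <- strrep("S", 15L)
  side <- function(ch, lo = 5L, hi = 12L) strrep(ch, sample(lo:hi, 1L))
  if (class == "GLOB") {
    return(strrep("I", sample(40:80, 1L)))
  }
  if (class == "SP") {
    return(paste0(signal, strrep("O", sample(30:60, 1L))))
  }
  membrane_ch <- if (class %in% c("BETA", "SP+BETA")) "B" else "M"
  k <- if (membrane_ch == "B") sample(c(8L, 10L, 12L), 1L) else {
    sample(1:12, 1L, prob = c(0.32, 0.2, 0.12, 0.08, 0.06, 0.05,
                              0.04, 0.04, 0.03, 0.02, 0.02, 0.02))
  }
  run_len <- if (membrane_ch == "B") 8L else 15L
  sides <- c("O", "I")
  start <- sample(1:2, 1L)
  parts <- side(sides[start])
  for (i in seq_len(k)) {
    nxt <- sides[((start + i - 1L) %% 2L) + 1L]
    parts <- c(parts, strrep(membrane_ch, run_len), side(nxt))
  }
  body <- paste(parts, collapse = "")
  if (startsWith(class, "SP")) {
    # mature chain of a secreted/anchored protein starts extracellular
    body <- sub("^I+", "", body)
    paste0(signal, body)
  } else {
    body
  }
}

random_aa_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

#' Simulate a desk-scale surface-proteome dataset
#'
#' Generates a MaxQuant-style protein-groups table, UniProt- and eggNOG-style
#' annotation tables, a 3line topology file and a ground-truth ledger with the
#' statistical structure the downstream analysis assumes. Intensities follow a
#' hierarchical model: protein log2 means are normal around
#' `base_log2_mean`, each protein's within-group variance is drawn from a
#' scaled-inverse-chi-square prior, and replicate values are normal around the
#' group mean. A value is recorded as missing with probability
#' `plogis((detection_limit - value) / censor_softness)` (plus an optional
#' MCAR rate); the negative-control condition is entirely missing. Missing
#' values are written as `0`, following the MaxQuant convention, and raw
#' intensities as `2^log2`.
#'
#' Planted X-specific proteins have `effect_log2fc` added to their BX group
#' mean and their BY group mean set far below the detection limit, so they are
#' absent by construction in BY. Planted transmembrane surface targets
#' additionally receive one GO identifier of interest and a transmembrane
#' topology; background proteins receive decoy GO identifiers only, except for
#' a small configurable leak rate.
#'
#' @param config A [sim_config()] object.
#' @param dir Optional output directory; when given, all five files are
#'   written there (`proteinGroups.txt`, `annotation_uniprot.tsv`,
#'   `annotation_eggnog.tsv`, `topology.3line`, `truth_ledger.tsv`).
#'
#' @return A list with elements `protein_groups` (the table as written, raw
#'   intensities with `0` for missing), `uniprot`, `eggnog` (annotation
#'   tibbles), `topology` (topology records, see [parse_3line()]), `ledger`
#'   (the truth ledger) and `paths` (named file paths, or `NULL`).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 30, seed = 7))
#' dim(sim$protein_groups)
simulate_dataset <- function(config, dir = NULL) {
  if (!inherits(config, "sim_config")) {
    abort_config("`config` must be created by sim_config()")
  }
  with_local_seed(config$seed, simulate_dataset_impl(config, dir))
}

simulate_dataset_impl <- function(config, dir) {
  conds <- config$conditions
  samples <- unlist(lapply(names(conds), function(cn) {
    paste0(cn, "_", seq_len(conds[[cn]]))
  }))
  sample_cond <- sub("_[0-9]+$", "", samples)
  lfq_cols <- paste0("LFQ intensity ", samples)
  n <- config$n_proteins

  empty_groups <- tibble::tibble(
    "Majority protein IDs" = character(0),
    "Razor + unique peptides" = integer(0),
    "Reverse" = character(0),
    "Potential contaminant" = character(0)
  )
  for (cl in lfq_cols) empty_groups[[cl]] <- numeric(0)

  if (n == 0L) {
    out <- list(
      protein_groups = empty_groups,
      uniprot = tibble::tibble(id = character(0), reviewed = logical(0),
                               gene = character(0), chromosome = character(0),
                               go_ids = character(0)),
      eggnog = tibble::tibble(id = character(0), go_ids = character(0)),
      topology = empty_topology_records(),
      ledger = empty_truth_ledger(),
      paths = NULL
    )
    if (!is.null(dir)) out$paths <- write_simulated_dataset(out, dir)
    return(out)
  }

  d0 <- config$within_group_sd_prior[["d0"]]
  s0 <- config$within_group_sd_prior[["s0"]]

  # --- identifiers and group structure (draw order is fixed so that common
  #     random numbers hold across configurations differing only in the
  #     detection limit) ---
  primary_ids <- sprintf("P%05d", seq_len(n))
  planted_idx <- if (config$n_bx_specific > 0) {
    sort(sample.int(n, config$n_bx_specific))
  } else integer(0)
  tm_surface_idx <- head(planted_idx, config$n_bx_specific_tm_surface)
  is_planted <- seq_len(n) %in% planted_idx
  is_tm_surface <- seq_len(n) %in% tm_surface_idx

  has_second <- !is_planted & runif(n) < config$multi_id_rate
  second_ids <- ifelse(has_second, sprintf("Q%05d", seq_len(n)), NA_character_)
  group_ids <- ifelse(has_second, paste0(primary_ids, ";", second_ids),
                      primary_ids)
  reviewed_primary <- runif(n) < 0.55
  reviewed_primary[is_tm_surface] <- TRUE
  reviewed_second <- runif(n) < 0.55
  unique_ids <- ifelse(
    reviewed_primary | !has_second, primary_ids,
    ifelse(reviewed_second, second_ids, primary_ids)
  )

  # --- hierarchical intensity model ---
  mu <- rnorm(n, config$base_log2_mean, config$between_protein_sd)
  sigma2 <- d0 * s0^2 / rchisq(n, df = d0)

  # --- topology ---
  classes <- sample(
    c("GLOB", "SP", "TM", "SP+TM", "BETA", "SP+BETA"), n, replace = TRUE,
    prob = c(0.55, 0.20, 0.15, 0.07, 0.02, 0.01)
  )
  classes[is_tm_surface] <- sample(c("TM", "SP+TM"), sum(is_tm_surface),
                                   replace = TRUE, prob = c(0.6, 0.4))
  topo_strings <- vapply(classes, simulate_topology_string, character(1))
  sequences <- vapply(nchar(topo_strings), random_aa_sequence, character(1))

  # --- GO annotation ---
  decoy_pool <- sprintf("GO:%07d", sample(1000000:1999999, max(4L * n, 50L)))
  interest_ids <- GO_INTEREST$go_id
  go_sets <- vector("list", n)
  for (i in seq_len(n)) {
    gos <- sample(decoy_pool, sample(1:6, 1L))
    leak <- runif(1) < config$go_leak_rate
    if (is_tm_surface[i] || leak) {
      gos <- c(sample(interest_ids, 1L), gos)
    }
    go_sets[[i]] <- gos
  }
  # split each GO ID across the two annotation sources
  src_split <- lapply(go_sets, function(gos) {
    sample(c("uniprot", "eggnog", "both"), length(gos), replace = TRUE,
           prob = c(0.4, 0.3, 0.3))
  })

  gene_names <- sprintf("GENE%04d", seq_len(n))
  chromosomes <- sample(c(as.character(1:29), "X", "Unplaced"), n,
                        replace = TRUE,
                        prob = c(rep(0.03, 29), 0.06, 0.07))

  # --- contaminant / reverse rows ---
  n_cont <- round(config$frac_contaminant * n)
  n_rev <- round(config$frac_reverse * n)
  cont_ids <- if (n_cont > 0) sprintf("CON__C%04d", seq_len(n_cont)) else character(0)
  rev_ids <- if (n_rev > 0) sprintf("REV__R%04d", seq_len(n_rev)) else character(0)
  mu_extra <- rnorm(n_cont + n_rev, config$base_log2_mean,
                    config$between_protein_sd)
  sigma2_extra <- d0 * s0^2 / rchisq(max(n_cont + n_rev, 1L), df = d0)
  sigma2_extra <- sigma2_extra[seq_len(n_cont + n_rev)]

  # --- replicate intensities, then censoring uniforms (common random
  #     numbers: the uniforms do not depend on the detection limit) ---
  all_ids <- c(group_ids, cont_ids, rev_ids)
  n_all <- length(all_ids)
  mu_all <- c(mu, mu_extra)
  sigma_all <- sqrt(c(sigma2, sigma2_extra))
  planted_all <- c(is_planted, rep(FALSE, n_cont + n_rev))
  by_mean_planted <- config$detection_limit - 8 * max(config$censor_softness, 0.25)

  group_mean <- matrix(mu_all, nrow = n_all, ncol = length(samples))
  colnames(group_mean) <- samples
  for (j in seq_along(samples)) {
    cond <- sample_cond[j]
    if (cond == "BX") {
      group_mean[planted_all, j] <- mu_all[planted_all] + config$effect_log2fc
    } else if (cond == "BY") {
      group_mean[planted_all, j] <- by_mean_planted
    }
  }

  values <- group_mean + matrix(rnorm(n_all * length(samples)),
                                nrow = n_all) * sigma_all
  u_censor <- matrix(runif(n_all * length(samples)), nrow = n_all)
  u_mcar <- matrix(runif(n_all * length(samples)), nrow = n_all)

  if (config$censor_softness > 0) {
    p_miss <- plogis((config$detection_limit - values) / config$censor_softness)
  } else {
    p_miss <- (values < config$detection_limit) * 1.0
  }
  missing <- u_censor < p_miss | u_mcar < config$mcar_rate
  missing[, sample_cond == config$control] <- TRUE  # no biotin, no signal

  raw <- ifelse(missing, 0, 2^values)

  protein_groups <- tibble::tibble(
    "Majority protein IDs" = all_ids,
    "Razor + unique peptides" = 2L,
    "Reverse" = c(rep("", n + n_cont), rep("+", n_rev)),
    "Potential contaminant" = c(rep("", n), rep("+", n_cont), rep("", n_rev))
  )
  for (j in seq_along(lfq_cols)) protein_groups[[lfq_cols[j]]] <- raw[, j]

  # --- annotation tables (keyed by individual majority IDs; GO carried on
  #     every ID of the group) ---
  join_go <- function(which_src) {
    vapply(seq_len(n), function(i) {
      keep <- src_split[[i]] %in% c(which_src, "both")
      paste(go_sets[[i]][keep], collapse = ";")
    }, character(1))
  }
  go_uni <- join_go("uniprot")
  go_egg <- join_go("eggnog")
  uniprot <- tibble::tibble(
    id = c(primary_ids, second_ids[has_second]),
    reviewed = c(reviewed_primary, reviewed_second[has_second]),
    gene = c(gene_names, gene_names[has_second]),
    chromosome = c(chromosomes, chromosomes[has_second]),
    go_ids = c(go_uni, go_uni[has_second])
  ) %>% dplyr::arrange(.data$id)
  eggnog <- tibble::tibble(
    id = c(primary_ids, second_ids[has_second]),
    go_ids = c(go_egg, go_egg[has_second])
  ) %>% dplyr::arrange(.data$id)

  topology <- topology_records_from_strings(unique_ids, classes, sequences,
                                            topo_strings)

  true_surface_go <- vapply(seq_len(n), function(i) {
    any(go_sets[[i]] %in% interest_ids)
  }, logical(1))
  lfc <- function(a, b) a - b  # first-minus-second convention
  mean_bu <- mu
  mean_bx <- ifelse(is_planted, mu + config$effect_log2fc, mu)
  mean_by <- ifelse(is_planted, by_mean_planted, mu)
  ledger <- tibble::tibble(
    protein_id = all_ids,
    unique_protein_id = c(unique_ids, cont_ids, rev_ids),
    profile = c(ifelse(is_planted, "bx_specific", "background"),
                rep("contaminant", n_cont), rep("reverse", n_rev)),
    is_planted_target = c(is_tm_surface, rep(FALSE, n_cont + n_rev)),
    true_log2fc_BU_BX = c(lfc(mean_bu, mean_bx), rep(0, n_cont + n_rev)),
    true_log2fc_BU_BY = c(lfc(mean_bu, mean_by), rep(0, n_cont + n_rev)),
    true_log2fc_BX_BY = c(lfc(mean_bx, mean_by), rep(0, n_cont + n_rev)),
    true_topology_class = c(classes, rep(NA_character_, n_cont + n_rev)),
    true_surface_go = c(true_surface_go, rep(FALSE, n_cont + n_rev)),
    true_mean = mu_all,
    true_sd = sigma_all
  )

  out <- list(protein_groups = protein_groups, uniprot = uniprot,
              eggnog = eggnog, topology = topology, ledger = ledger,
              paths = NULL)
  if (!is.null(dir)) out$paths <- write_simulated_dataset(out, dir)
  out
}

write_simulated_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    protein_groups = file.path(dir, "proteinGroups.txt"),
    uniprot = file.path(dir, "annotation_uniprot.tsv"),
    eggnog = file.path(dir, "annotation_eggnog.tsv"),
    topology = file.path(dir, "topology.3line"),
    ledger = file.path(dir, "truth_ledger.tsv")
  )
  readr::write_tsv(sim$protein_groups, paths[["protein_groups"]])
  readr::write_tsv(sim$uniprot, paths[["uniprot"]])
  readr::write_tsv(sim$eggnog, paths[["eggnog"]])
  write_3line(sim$topology, paths[["topology"]])
  readr::write_tsv(sim$ledger, paths[["ledger"]])
  paths
}

empty_truth_ledger <- function() {
  tibble::tibble(
    protein_id = character(0), unique_protein_id = character(0),
    profile = character(0), is_planted_target = logical(0),
    true_log2fc_BU_BX = numeric(0), true_log2fc_BU_BY = numeric(0),
    true_log2fc_BX_BY = numeric(0), true_topology_class = character(0),
    true_surface_go = logical(0), true_mean = numeric(0), true_sd = numeric(0)
  )
}

#' Planted marker candidates of a simulated dataset
#'
#' Returns the protein-group identifiers of the planted transmembrane,
#' surface-annotated, X-specific proteins, i.e. the ground-truth set the
#' prioritized candidate tier should recover.
#'
#' @param ledger A truth ledger from [simulate_dataset()].
#' @return Character vector of protein IDs (possibly empty).
#' @export
planted_target_set <- function(ledger) {
  if (!is.data.frame(ledger) || !all(c("protein_id", "is_planted_target") %in%
                                     names(ledger))) {
    abort_input("`ledger` must be a truth ledger with protein_id and is_planted_target")
  }
  if (nrow(ledger) == 0L) {
    abort_input("`ledger` is empty")
  }
  ledger$protein_id[ledger$is_planted_target]
}
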