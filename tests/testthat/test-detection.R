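# Detection must rely on observed cells only; Venn regions must partition the
# retained set; the heatmap set is the union of its three membership reasons.

test_that("detection counts come from the observed mask only", {
  m <- rbind(
    bx2 = c(NA, NA, NA, 2^0 * 20, 21, NA, NA, NA, NA),
    none = rep(NA_real_, 9)
  )
  colnames(m) <- c(paste0("BU_", 1:3), paste0("BX_", 1:3), paste0("BY_", 1:3))
  long <- intensity_from_matrix(m)
  # impute everything so imputed cells exist; detection must ignore them
  long$log2_intensity[!long$observed] <- 15
  long$imputed[!long$observed] <- TRUE
  prof <- detection_profiles(long)
  bx2 <- prof[prof$protein_id == "bx2", ]
  expect_equal(bx2$n_detected[bx2$condition == "BX"], 2)
  expect_equal(bx2$n_detected[bx2$condition == "BU"], 0)
  none <- prof[prof$protein_id == "none", ]
  expect_true(all(none$n_detected == 0))
})

test_that("profile counts equal a brute-force mask recount on simulated data", {
  sim <- simulate_dataset(sim_config(n_proteins = 120, seed = 11))
  long <- sim$protein_groups %>%
    remove_decoys_and_contaminants() %>%
    pivot_intensities()
  prof <- detection_profiles(long)
  tab <- sim$protein_groups
  tab <- tab[tab$Reverse != "+" & tab$`Potential contaminant` != "+", ]
  for (cond in c("BU", "BX", "BY")) {
    cols <- grep(paste0("^LFQ intensity ", cond, "_"), names(tab))
    brute <- rowSums(tab[, cols] > 0)
    sub <- prof[prof$condition == cond, ]
    idx <- match(tab$`Majority protein IDs`, sub$protein_id)
    expect_equal(sub$n_detected[idx], unname(brute), label = cond)
  }
})

test_that("venn regions are disjoint, exhaustive, and correctly classified", {
  prof <- profiles_from_counts(
    c("bxonly", "bxy", "all", "nothing"),
    bx = c(2L, 1L, 3L, 0L), by = c(0L, 2L, 1L, 0L), bu = c(0L, 0L, 2L, 0L)
  )
  venn <- venn_partition(prof)
  get <- function(r) venn$n[venn$region == r]
  expect_equal(get("BX"), 1)
  expect_equal(get("BX&BY"), 1)   # detected in BX and BY but not BU
  expect_equal(get("BU&BX&BY"), 1)
  expect_equal(get("none"), 1)
  expect_equal(sum(venn$n), 4)

  sim <- simulate_dataset(sim_config(n_proteins = 90, seed = 6))
  long <- sim$protein_groups %>%
    remove_decoys_and_contaminants() %>%
    pivot_intensities()
  venn2 <- venn_partition(detection_profiles(long))
  expect_equal(sum(venn2$n), dplyr::n_distinct(long$protein_id))
})

test_that("exclusive sets follow the detection flags and are disjoint", {
  prof <- profiles_from_counts(
    c("bxonly", "mixed", "shared", "buonly"),
    bx = c(3L, 2L, 2L, 0L), by = c(0L, 1L, 0L, 0L), bu = c(0L, 2L, 2L, 1L)
  )
  sets <- exclusive_sets(prof)
  row <- function(p) sets[sets$protein_id == p, ]
  expect_true(row("bxonly")$bx_only)
  expect_true(row("bxonly")$absent_in_BY)
  expect_false(any(unlist(row("mixed")[, c("bx_only", "bu_only",
                                           "bx_and_bu")])))
  expect_true(row("shared")$bx_and_bu)
  expect_true(row("buonly")$bu_only)
  expect_true(all(rowSums(sets[, c("bx_only", "bu_only", "bx_and_bu")]) <= 1))
})

test_that("planted X-specific proteins land in the BY-absence set", {
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    sim <- simulate_dataset(sim_config(n_proteins = 200, seed = seed))
    long <- sim$protein_groups %>%
      remove_decoys_and_contaminants() %>%
      pivot_intensities()
    sets <- exclusive_sets(detection_profiles(long))
    planted <- sim$ledger$protein_id[sim$ledger$profile == "bx_specific"]
    absent <- sets$protein_id[sets$absent_in_BY]
    hits <- hits + sum(planted %in% absent)
    total <- total + length(planted)
  }
  expect_gte(hits / total, 0.9)
})

test_that("the heatmap set unions its reasons and clusters duplicates together", {
  sim <- simulate_dataset(sim_config(n_proteins = 150, seed = 3))
  long <- sim$protein_groups %>%
    remove_decoys_and_contaminants() %>%
    pivot_intensities() %>%
    valid_value_filter() %>%
    impute_missing(seed = 3)
  res <- run_diffexpr(long)
  prof <- detection_profiles(long)
  hm <- build_heatmap_set(long, res, prof)

  sig <- unique(res$protein_id[res$significant])
  sets <- exclusive_sets(prof)
  sets <- sets[sets$protein_id %in% unique(long$protein_id), ]
  expected_members <- union(sig, sets$protein_id[sets$absent_in_BX |
                                                   sets$absent_in_BY])
  expect_setequal(hm$members$protein_id, expected_members)
  expect_setequal(hm$row_order, expected_members)
  expect_true(all(lengths(hm$members$reasons) >= 1))

  # z rows standardized over non-missing cells
  zstats <- hm$z %>%
    dplyr::filter(is.finite(.data$z)) %>%
    dplyr::group_by(.data$protein_id) %>%
    dplyr::summarise(m = mean(.data$z), s = sd(.data$z), .groups = "drop")
  expect_true(all(abs(zstats$m) < 1e-8))
  expect_true(all(abs(zstats$s - 1) < 1e-8))

  # duplicated rows sit adjacent in the dendrogram order
  long2 <- long
  dup <- long2[long2$protein_id == hm$members$protein_id[1], ]
  dup$protein_id <- "DUPLICATE"
  long2 <- dplyr::bind_rows(long2, dup)
  prof2 <- detection_profiles(long2)
  res2 <- dplyr::bind_rows(res, dplyr::mutate(
    res[res$protein_id == hm$members$protein_id[1], ],
    protein_id = "DUPLICATE"))
  hm2 <- build_heatmap_set(long2, res2, prof2)
  pos <- match(c(hm$members$protein_id[1], "DUPLICATE"), hm2$row_order)
  expect_equal(abs(diff(pos)), 1)
})

test_that("an empty result set yields an empty heatmap set", {
  long <- intensity_from_matrix(two_group_matrix(4, 25, 25, 1))
  long$condition <- sub("_[0-9]+$", "", long$sample_id)
  res <- tibble::tibble(protein_id = character(0), contrast = character(0),
                        log2fc = numeric(0), significant = logical(0))
  prof <- profiles_from_counts(unique(long$protein_id),
                               bx = rep(2L, 4), by = rep(2L, 4),
                               bu = rep(2L, 4))
  hm <- build_heatmap_set(long, res, prof)
  expect_equal(nrow(hm$members), 0)
  expect_length(hm$row_order, 0)
})
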