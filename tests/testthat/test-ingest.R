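# Reading, decoy removal, valid-value filtering and downshifted-normal
# imputation. Observed values must never be modified by any ingest step.

write_pg_fixture <- function(rows, path = withr::local_tempfile(
                               fileext = ".tsv",
                               .local_envir = parent.frame())) {
  readr::write_tsv(rows, path)
  path
}

pg_row <- function(id, bu, bx, by, rev = "", con = "") {
  out <- tibble::tibble("Majority protein IDs" = id, Reverse = rev,
                        "Potential contaminant" = con)
  for (i in 1:3) out[[paste0("LFQ intensity BU_", i)]] <- bu[i]
  for (i in 1:3) out[[paste0("LFQ intensity BX_", i)]] <- bx[i]
  for (i in 1:3) out[[paste0("LFQ intensity BY_", i)]] <- by[i]
  out
}

test_that("zero LFQ cells read as missing and IDs are preserved verbatim", {
  tab <- pg_row("sp|P1;tr|Q1", c(0, 2^20, 2^21), c(0, 0, 0), c(2^19, 0, 0))
  parsed <- read_protein_groups(write_pg_fixture(tab))
  expect_identical(parsed$`Majority protein IDs`, "sp|P1;tr|Q1")
  expect_true(is.na(parsed$`LFQ intensity BU_1`))
  expect_equal(parsed$`LFQ intensity BU_2`, 2^20)
  expect_true(is.na(parsed$`LFQ intensity BX_1`))
})

test_that("format errors name the missing column and the unreadable row", {
  tab <- pg_row("P1", c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  bad <- tab[, setdiff(names(tab), "Majority protein IDs")]
  expect_error(read_protein_groups(write_pg_fixture(bad)),
               "Majority protein IDs", class = "surfmark_format_error")

  tab2 <- tab
  tab2$`LFQ intensity BU_1` <- "not-a-number"
  expect_error(read_protein_groups(write_pg_fixture(tab2)),
               "row 1", class = "surfmark_format_error")
})

test_that("simulated tables round-trip through write and read", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(n_proteins = 50, seed = 13), dir = dir)
  parsed <- read_protein_groups(sim$paths[["protein_groups"]])
  expect_equal(nrow(parsed), nrow(sim$protein_groups))
  lfq <- grep("^LFQ intensity ", names(parsed), value = TRUE)
  for (cl in lfq) {
    orig <- sim$protein_groups[[cl]]
    expect_identical(is.na(parsed[[cl]]), orig == 0, label = cl)
    expect_equal(parsed[[cl]][orig > 0], orig[orig > 0], label = cl)
  }
})

test_that("decoy and contaminant removal counts rows once, reverse first", {
  tab <- dplyr::bind_rows(
    pg_row("P1", c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)),
    pg_row("P2", c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), rev = "+"),
    pg_row("P3", c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), rev = "+", con = "+"),
    pg_row("P4", c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), con = "+"),
    pg_row("P5", c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  )
  out <- remove_decoys_and_contaminants(tab)
  rep <- filter_report(out)
  expect_equal(nrow(out), 2)
  expect_equal(rep$n_reverse_removed, 2)       # P3 counted under reverse
  expect_equal(rep$n_contaminant_removed, 1)
  expect_equal(rep$n_input, 5)

  clean <- dplyr::bind_rows(pg_row("A", c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)))
  expect_equal(nrow(remove_decoys_and_contaminants(clean)), 1)
})

test_that("valid-value filter applies the >=2-in-some-condition rule", {
  tab <- dplyr::bind_rows(
    pg_row("keep2bu", c(2^20, 2^20, 0), c(0, 0, 0), c(0, 0, 0)),
    pg_row("drop1each", c(2^20, 0, 0), c(2^20, 0, 0), c(2^20, 0, 0)),
    pg_row("keep3bx", c(0, 0, 0), c(2^20, 2^21, 2^20), c(0, 0, 0))
  )
  long <- pivot_intensities(read_protein_groups(write_pg_fixture(tab)))
  filtered <- valid_value_filter(long, min_valid = 2)
  kept <- unique(filtered$protein_id)
  expect_setequal(kept, c("keep2bu", "keep3bx"))
  expect_equal(filter_report(filtered)$n_failed_valid_filter, 1)
  expect_error(valid_value_filter(long, min_valid = 4),
               class = "surfmark_config_error")
})

test_that("retained count equals a brute-force recount over the mask", {
  sim <- simulate_dataset(sim_config(n_proteins = 300, seed = 7))
  long <- sim$protein_groups %>%
    remove_decoys_and_contaminants() %>%
    pivot_intensities()
  filtered <- valid_value_filter(long, min_valid = 2)

  # independent scan on the raw table
  tab <- sim$protein_groups
  tab <- tab[tab$Reverse != "+" & tab$`Potential contaminant` != "+", ]
  conds <- c("BU", "BX", "BY")
  pass <- vapply(seq_len(nrow(tab)), function(i) {
    any(vapply(conds, function(cn) {
      cols <- grep(paste0("^LFQ intensity ", cn, "_"), names(tab))
      sum(tab[i, cols] > 0) >= 2
    }, logical(1)))
  }, logical(1))
  expect_equal(dplyr::n_distinct(filtered$protein_id), sum(pass))
  expect_setequal(unique(filtered$protein_id),
                  tab$`Majority protein IDs`[pass])
})

test_that("imputation fills exactly the closed-form value when width is zero", {
  sim <- simulate_dataset(sim_config(n_proteins = 120, seed = 3))
  long <- sim$protein_groups %>%
    remove_decoys_and_contaminants() %>%
    pivot_intensities() %>%
    valid_value_filter()
  imp <- impute_missing(long, downshift = 1.8, width = 0, seed = 1)
  by_sample <- split(imp, imp$sample_id)
  for (s in by_sample) {
    if (!any(s$imputed)) next
    mean_s <- mean(s$log2_intensity[s$observed])
    sd_s <- sd(s$log2_intensity[s$observed])
    expect_equal(unique(s$log2_intensity[s$imputed]), mean_s - 1.8 * sd_s,
                 tolerance = 1e-12)
  }
})

test_that("imputation is seeded, leaves observed values alone, and flags masks", {
  sim <- simulate_dataset(sim_config(n_proteins = 100, seed = 8))
  long <- sim$protein_groups %>%
    remove_decoys_and_contaminants() %>%
    pivot_intensities() %>%
    valid_value_filter()
  a <- impute_missing(long, seed = 42)
  b <- impute_missing(long, seed = 42)
  expect_identical(a, b)
  obs_key <- paste(long$protein_id, long$sample_id)
  a_key <- paste(a$protein_id, a$sample_id)
  idx <- match(obs_key[long$observed], a_key)
  expect_identical(a$log2_intensity[idx],
                   long$log2_intensity[long$observed])
  expect_true(all(!a$imputed[idx]))
  expect_true(all(a$imputed[!a$observed & a$condition != "BC"]))
  expect_true(all(is.na(a$log2_intensity[a$condition == "BC"])))

  no_missing <- intensity_from_matrix(two_group_matrix(10, 25, 25, 1))
  out <- impute_missing(no_missing, seed = 1)
  expect_false(any(out$imputed))
})

test_that("a sample with fewer than two observed values raises an imputation error", {
  m <- two_group_matrix(5, 25, 25, 1)
  m[1:4, "BX_1"] <- NA
  long <- intensity_from_matrix(m)
  expect_error(impute_missing(long, seed = 1), "BX_1",
               class = "surfmark_imputation_error")
})

test_that("imputed values sit below the observed mean (sign test over seeds)", {
  successes <- 0L
  for (seed in 1:20) {
    sim <- simulate_dataset(sim_config(n_proteins = 300, seed = seed))
    long <- sim$protein_groups %>%
      remove_decoys_and_contaminants() %>%
      pivot_intensities() %>%
      valid_value_filter()
    imp <- impute_missing(long, seed = seed)
    cmp <- imp %>%
      dplyr::filter(.data$condition != "BC") %>%
      dplyr::group_by(.data$sample_id) %>%
      dplyr::summarise(
        below = mean(.data$log2_intensity[.data$imputed]) <
          mean(.data$log2_intensity[.data$observed]),
        any_imputed = any(.data$imputed), .groups = "drop")
    if (all(cmp$below[cmp$any_imputed])) successes <- successes + 1L
  }
  expect_gte(successes, 19)
})

test_that("decoy removal and the valid-value filter commute", {
  sim <- simulate_dataset(sim_config(n_proteins = 150, seed = 17))
  a <- sim$protein_groups %>%
    remove_decoys_and_contaminants() %>%
    pivot_intensities() %>%
    valid_value_filter()
  b <- sim$protein_groups %>%
    pivot_intensities() %>%
    valid_value_filter()
  flagged <- sim$protein_groups$`Majority protein IDs`[
    sim$protein_groups$Reverse == "+" |
      sim$protein_groups$`Potential contaminant` == "+"]
  expect_setequal(unique(a$protein_id),
                  setdiff(unique(b$protein_id), flagged))
})
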