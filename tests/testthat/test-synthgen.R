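# The generator must reproduce the statistical structure the analysis
# assumes: hierarchical log-normal intensities, logistic detection-limit
# censoring, an all-missing negative control, flagged decoy/contaminant rows
# and a faithful truth ledger.

lfq_cols_of <- function(tab, cond) {
  grep(paste0("^LFQ intensity ", cond, "_"), names(tab), value = TRUE)
}

test_that("empty configuration yields empty outputs with valid headers", {
  sim <- simulate_dataset(sim_config(n_proteins = 0, n_bx_specific = 0,
                                     n_bx_specific_tm_surface = 0, seed = 1))
  expect_equal(nrow(sim$protein_groups), 0)
  expect_true(all(c("Majority protein IDs", "Reverse", "Potential contaminant")
                  %in% names(sim$protein_groups)))
  expect_length(lfq_cols_of(sim$protein_groups, "BX"), 3)
  expect_equal(nrow(sim$ledger), 0)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n_proteins = -1), "n_proteins",
               class = "surfmark_config_error")
  expect_error(sim_config(frac_contaminant = 1.5), "frac_contaminant",
               class = "surfmark_config_error")
  expect_error(sim_config(n_bx_specific = 5, n_bx_specific_tm_surface = 6),
               "n_bx_specific_tm_surface", class = "surfmark_config_error")
  expect_error(sim_config(conditions = c(BC = 3, BU = 1, BX = 3, BY = 3)),
               "replicate count", class = "surfmark_config_error")
})

test_that("hard censoring below all values leaves no missing cells outside the control", {
  sim <- simulate_dataset(sim_config(n_proteins = 60, censor_softness = 0,
                                     detection_limit = 0, n_bx_specific = 0,
                                     n_bx_specific_tm_surface = 0, seed = 2))
  tab <- sim$protein_groups
  bc <- unlist(tab[lfq_cols_of(tab, "BC")])
  rest <- unlist(tab[c(lfq_cols_of(tab, "BU"), lfq_cols_of(tab, "BX"),
                       lfq_cols_of(tab, "BY"))])
  expect_true(all(bc == 0))
  expect_true(all(rest > 0))
})

test_that("missing fraction matches the analytic censoring expectation", {
  cfg <- sim_config(n_proteins = 500, seed = 1)
  sim <- simulate_dataset(cfg)
  d0 <- cfg$within_group_sd_prior[["d0"]]
  s0 <- cfg$within_group_sd_prior[["s0"]]

  # numeric integration of the logistic censoring over the marginal
  # intensity distribution (protein mean spread x within-group variance
  # drawn from the scaled-inverse-chi-square prior)
  sichisq_density <- function(v) {
    (d0 * s0^2 / 2)^(d0 / 2) / gamma(d0 / 2) *
      v^(-d0 / 2 - 1) * exp(-d0 * s0^2 / (2 * v))
  }
  p_missing <- function(center, between_sd) {
    f <- function(v) {
      sdx <- sqrt(v + between_sd^2)
      vapply(seq_along(v), function(i) {
        stats::integrate(function(x) {
          plogis((cfg$detection_limit - x) / cfg$censor_softness) *
            dnorm(x, center, sdx[i])
        }, center - 12 * sdx[i], center + 12 * sdx[i])$value
      }, numeric(1))
    }
    stats::integrate(function(v) f(v) * sichisq_density(v), 0, Inf,
                     rel.tol = 1e-8)$value
  }
  p_bg <- p_missing(cfg$base_log2_mean, cfg$between_protein_sd)
  p_bx_planted <- p_missing(cfg$base_log2_mean + cfg$effect_log2fc,
                            cfg$between_protein_sd)
  by_mean <- cfg$detection_limit - 8 * max(cfg$censor_softness, 0.25)
  p_by_planted <- p_missing(by_mean, 0)

  n_pl <- cfg$n_bx_specific
  n_bg <- cfg$n_proteins - n_pl
  total_cells <- cfg$n_proteins * 9
  expected <- (n_bg * 9 * p_bg +
                 n_pl * 3 * (p_bg + p_bx_planted + p_by_planted)) / total_cells

  genuine <- sim$ledger$profile %in% c("background", "bx_specific")
  tab <- sim$protein_groups[genuine, ]
  cells <- unlist(tab[c(lfq_cols_of(tab, "BU"), lfq_cols_of(tab, "BX"),
                        lfq_cols_of(tab, "BY"))])
  expect_lt(abs(mean(cells == 0) - expected), 0.05)
})

test_that("identical configurations reproduce byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(n_proteins = 80, seed = 11)
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("lowering the detection limit never increases missingness", {
  count_missing <- function(dl) {
    sim <- simulate_dataset(sim_config(n_proteins = 200, detection_limit = dl,
                                       seed = 5))
    tab <- sim$protein_groups
    sum(unlist(tab[c(lfq_cols_of(tab, "BU"), lfq_cols_of(tab, "BX"),
                     lfq_cols_of(tab, "BY"))]) == 0)
  }
  dls <- c(26, 24, 22, 20, 18)
  counts <- vapply(dls, count_missing, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("control columns are fully missing and decoy rows are flagged", {
  cfg <- sim_config(n_proteins = 100, frac_contaminant = 0.1,
                    frac_reverse = 0.05, seed = 9)
  sim <- simulate_dataset(cfg)
  tab <- sim$protein_groups
  expect_true(all(unlist(tab[lfq_cols_of(tab, "BC")]) == 0))
  expect_equal(sum(tab$Reverse == "+"), 5)
  expect_equal(sum(tab$`Potential contaminant` == "+"), 10)
  expect_true(all(startsWith(
    tab$`Majority protein IDs`[tab$Reverse == "+"], "REV__")))
})

test_that("within-group variances follow the scaled-inverse-chi-square prior", {
  cfg <- sim_config(n_proteins = 5000, seed = 21)
  sim <- simulate_dataset(cfg)
  d0 <- cfg$within_group_sd_prior[["d0"]]
  s0 <- cfg$within_group_sd_prior[["s0"]]
  genuine <- sim$ledger$profile %in% c("background", "bx_specific")
  v <- sim$ledger$true_sd[genuine]^2
  # v ~ d0 s0^2 / chisq(d0)  <=>  d0 s0^2 / v ~ chisq(d0)
  ks <- suppressWarnings(stats::ks.test(d0 * s0^2 / v, "pchisq", df = d0))
  expect_gt(ks$p.value, 0.01)
})

test_that("the planted target set is recovered from the ledger", {
  cfg <- sim_config(n_proteins = 150, n_bx_specific = 10,
                    n_bx_specific_tm_surface = 5, seed = 4)
  sim <- simulate_dataset(cfg)
  targets <- planted_target_set(sim$ledger)
  expect_length(targets, 5)
  expect_false(any(grepl("^(CON|REV)__", targets)))
  tm_classes <- c("TM", "SP+TM", "BETA", "SP+BETA")
  led <- sim$ledger[sim$ledger$protein_id %in% targets, ]
  expect_true(all(led$true_topology_class %in% tm_classes))
  expect_true(all(led$true_surface_go))

  no_planted <- simulate_dataset(sim_config(n_proteins = 30, n_bx_specific = 0,
                                            n_bx_specific_tm_surface = 0,
                                            seed = 4))
  expect_length(planted_target_set(no_planted$ledger), 0)
})
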