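# The surface-accessibility disjunction and candidate tiers, including the
# bundled worked example (19 candidates -> 7 transmembrane, 5 prioritized).

test_that("accessibility follows the three-part disjunction", {
  interest <- interest_from_categories(list("CS", "PM", "ES", "PM", "ES"))
  topo <- topo_from_specs(
    interest$protein_id,
    c("GLOB", "GLOB", "TM", "TM", "GLOB"),
    outside = c(FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  acc <- surface_accessible(interest, topo)
  # CS + globular: accessible (first disjunct)
  expect_true(acc$surface_accessible[1])
  # PM + globular, no outside region: not accessible
  expect_false(acc$surface_accessible[2])
  # ES + transmembrane: accessible (third disjunct)
  expect_true(acc$surface_accessible[3])
  # PM + transmembrane: accessible (second disjunct)
  expect_true(acc$surface_accessible[4])
  # ES alone, globular: neither accessible nor of interest
  expect_false(acc$surface_accessible[5])
  expect_false(acc$of_interest[5])
  expect_true(acc$of_interest[3])  # ES + TM resolves to of-interest
})

test_that("a PM protein with an outside region is accessible without TM topology", {
  interest <- interest_from_categories(list("PM"))
  topo <- topo_from_specs(interest$protein_id, "SP", outside = TRUE)
  acc <- surface_accessible(interest, topo)
  expect_true(acc$surface_accessible)
})

test_that("missing topology is treated as globular-unknown with a warning", {
  interest <- interest_from_categories(list("CS", "ES"))
  topo <- topo_from_specs(interest$protein_id[1], "GLOB", outside = FALSE)
  expect_warning(acc <- surface_accessible(interest, topo), "topology")
  expect_true(acc$surface_accessible[1])   # CS needs no topology
  expect_false(acc$surface_accessible[2])  # ES with unknown topology: no
})

test_that("the worked example yields 7 transmembrane and the 5 prioritized candidates", {
  inp <- candidate_example_inputs()
  calls <- call_targets(inp$profiles, inp$interest, inp$topo)
  expect_equal(nrow(calls), 19)
  expect_equal(sum(calls$is_transmembrane), 7)
  expect_setequal(calls$protein_id[calls$tier == "prioritized"],
                  c("O77780", "F1N3G6", "D3K0R6", "Q03763", "Q3MHW6"))
  expect_true(all(calls$tier >= "accessible"))
  # one BX replicate keeps a transmembrane protein out of the top tier
  q3 <- calls[calls$protein_id == "Q3T0C6", ]
  expect_true(q3$is_transmembrane)
  expect_equal(as.character(q3$tier), "accessible")
})

test_that("any BY detection disqualifies a protein regardless of evidence", {
  interest <- interest_from_categories(list("CS"))
  topo <- topo_from_specs(interest$protein_id, "TM", outside = TRUE)
  prof <- profiles_from_counts(interest$protein_id, bx = 3L, by = 1L)
  calls <- call_targets(prof, interest, topo)
  expect_equal(as.character(calls$tier), "none")
})

test_that("a globular planted protein never reaches the prioritized tier", {
  interest <- interest_from_categories(list("CS"))
  topo <- topo_from_specs(interest$protein_id, "GLOB", outside = FALSE)
  prof <- profiles_from_counts(interest$protein_id, bx = 3L, by = 0L)
  calls <- call_targets(prof, interest, topo)
  expect_equal(as.character(calls$tier), "accessible")
})

test_that("the engine agrees with the brute-force oracle on random cases", {
  set.seed(23)
  all_cats <- unique(go_interest_terms()$category)
  classes <- c("TM", "SP+TM", "GLOB", "SP", "BETA", "SP+BETA")
  for (i in 1:200) {
    cats <- sample(all_cats, sample(0:4, 1))
    cls <- sample(classes, 1)
    outside <- if (cls == "GLOB") FALSE else sample(c(TRUE, FALSE), 1)
    n_bx <- sample(0:3, 1); n_by <- sample(0:3, 1)
    interest <- interest_from_categories(list(cats))
    topo <- topo_from_specs(interest$protein_id, cls, outside)
    prof <- profiles_from_counts(interest$protein_id, n_bx, n_by)
    calls <- call_targets(prof, interest, topo)
    oracle <- target_oracle(cats, cls, topo$tmr_count, outside, n_bx, n_by)
    expect_equal(calls$surface_accessible, oracle$surface_accessible,
                 label = paste("accessible case", i))
    expect_equal(as.character(calls$tier), oracle$tier,
                 label = paste("tier case", i))
  }
})

test_that("tiers are monotone in GO categories and BX replicates", {
  set.seed(31)
  all_cats <- unique(go_interest_terms()$category)
  classes <- c("TM", "SP+TM", "GLOB", "SP")
  tier_of <- function(cats, cls, outside, bx, by) {
    interest <- interest_from_categories(list(cats))
    topo <- topo_from_specs(interest$protein_id, cls, outside)
    calls <- call_targets(profiles_from_counts(interest$protein_id, bx, by),
                          interest, topo)
    calls$tier
  }
  for (i in 1:60) {
    cats <- sample(all_cats, sample(0:3, 1))
    cls <- sample(classes, 1)
    outside <- cls != "GLOB"
    bx <- sample(0:2, 1); by <- 0L
    base <- tier_of(cats, cls, outside, bx, by)
    more_go <- tier_of(union(cats, sample(all_cats, 1)), cls, outside, bx, by)
    more_bx <- tier_of(cats, cls, outside, bx + 1L, by)
    expect_gte(as.integer(more_go), as.integer(base))
    expect_gte(as.integer(more_bx), as.integer(base))
  }
})

test_that("direction BY swaps the roles of the sexed conditions", {
  interest <- interest_from_categories(list("CS"))
  topo <- topo_from_specs(interest$protein_id, "TM", outside = TRUE)
  prof <- profiles_from_counts(interest$protein_id, bx = 0L, by = 3L)
  calls_bx <- call_targets(prof, interest, topo, direction = "BX")
  calls_by <- call_targets(prof, interest, topo, direction = "BY")
  expect_equal(as.character(calls_bx$tier), "none")
  expect_equal(as.character(calls_by$tier), "prioritized")
})

test_that("the selection report sorts by tier and flags X-linked candidates", {
  inp <- candidate_example_inputs()
  calls <- call_targets(inp$profiles, inp$interest, inp$topo)
  rep <- selection_report(calls, inp$interest)
  expect_equal(as.character(rep$tier[1:5]), rep("prioritized", 5))
  expect_true(rep$x_linked[rep$protein_id == "F1N3G6"])
  expect_false(any(rep$x_linked[rep$protein_id != "F1N3G6"]))
  empty <- selection_report(calls[0, ], inp$interest)
  expect_equal(nrow(empty), 0)
  expect_true("x_linked" %in% names(empty))
})
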