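# Fixture builders and independent oracles shared across test files. The
# oracles deliberately use the most direct formulation available (explicit
# enumeration, definitional sums, straight if-else rules) and never call the
# implementation paths they check.

# Long intensity tibble from a log2 matrix (NA = missing); sample names like
# "BU_1" carry the condition prefix.
intensity_from_matrix <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  out <- tidyr::pivot_longer(
    tibble::rownames_to_column(as.data.frame(m), "protein_id"),
    -"protein_id", names_to = "sample_id", values_to = "log2_intensity"
  )
  out$condition <- sub("_[0-9]+$", "", out$sample_id)
  out$observed <- !is.na(out$log2_intensity)
  out$imputed <- FALSE
  out
}

# Two-group matrix with given group means and SD.
two_group_matrix <- function(n, mean1, mean2, sd, conds = c("BU", "BX"),
                             reps = 3) {
  m <- cbind(
    matrix(rnorm(n * reps, mean1, sd), n),
    matrix(rnorm(n * reps, mean2, sd), n)
  )
  colnames(m) <- c(paste0(conds[1], "_", seq_len(reps)),
                   paste0(conds[2], "_", seq_len(reps)))
  rownames(m) <- sprintf("P%04d", seq_len(n))
  m
}

# Definitional step-up BH (independent of stats::p.adjust).
bh_definitional <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, m * p[o[k]] / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# Two-sided Fisher p by a literal choose()-based sum over the support.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b; N <- m + nn
  supp <- max(0, k - nn):min(k, m)
  dens <- choose(m, supp) * choose(nn, k - supp) / choose(N, k)
  d_obs <- choose(m, a) * choose(nn, k - a) / choose(N, k)
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

# Score an explicit gapped alignment: substitution scores over non-gap
# columns plus, per maximal gap run of length L in either row, a cost of
# open + L * ext.
score_gapped <- function(qa, qb, sub, open, ext) {
  stopifnot(length(qa) == length(qb))
  both <- qa != "-" & qb != "-"
  s <- sum(vapply(which(both), function(k) sub[qa[k], qb[k]], numeric(1)))
  for (g in list(rle(qa == "-"), rle(qb == "-"))) {
    runs <- g$lengths[g$values]
    s <- s - sum(open + runs * ext)
  }
  s
}

# Exhaustive alignment enumeration: maximum score over all global alignments
# of a and b (vectors of residues), scoring each alignment path directly.
enumerate_best_score <- function(a, b, sub, open, ext) {
  best <- -Inf
  recurse <- function(i, j, qa, qb) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score_gapped(qa, qb, sub, open, ext))
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      recurse(i + 1, j + 1, c(qa, a[i]), c(qb, b[j]))
    }
    if (i <= length(a)) recurse(i + 1, j, c(qa, a[i]), c(qb, "-"))
    if (j <= length(b)) recurse(i, j + 1, c(qa, "-"), c(qb, b[j]))
  }
  recurse(1, 1, character(0), character(0))
  best
}

# Straight-line re-statement of the interest rule for one GO set.
interest_oracle <- function(go_set) {
  terms <- go_interest_terms()
  cats <- unique(terms$category[terms$go_id %in% go_set])
  direct_cats <- c("PM", "CS", "ESPM", "ECESPM", "ACPM", "ACESPM", "ICESPM",
                   "ICPM", "ESCW", "ESCOM")
  list(
    categories = cats,
    direct = any(cats %in% direct_cats),
    es = "ES" %in% cats
  )
}

# Straight-line re-statement of the accessibility + tier rules.
target_oracle <- function(categories, topo_class, tmr_count,
                          has_outside, n_bx, n_by, min_bx_reps = 2) {
  tm <- topo_class %in% c("TM", "SP+TM", "BETA", "SP+BETA") && tmr_count >= 1
  accessible_go <-
    any(categories %in% c("CS", "ESPM", "ECESPM", "ACESPM", "ICESPM",
                          "ESCW", "ESCOM")) ||
    (any(categories %in% c("PM", "ACPM", "ICPM")) && (tm || has_outside)) ||
    ("ES" %in% categories && tm)
  tier <- "none"
  if (accessible_go && n_bx >= 1 && n_by == 0) {
    tier <- "accessible"
    if (n_bx >= min_bx_reps && tm) tier <- "prioritized"
  }
  list(surface_accessible = accessible_go, tier = tier, is_transmembrane = tm)
}

# Minimal interest-calls tibble straight from category subsets (one
# representative GO ID per category).
interest_from_categories <- function(cat_sets) {
  terms <- go_interest_terms()
  rep_id <- tapply(terms$go_id, terms$category, function(x) x[1])
  tb <- tibble::tibble(
    protein_id = sprintf("P%05d", seq_along(cat_sets)),
    go_union = lapply(cat_sets, function(cc) unname(rep_id[cc]))
  )
  classify_interest(tb)
}

# Topology records built directly from class/outside specs.
topo_from_specs <- function(ids, classes, outside) {
  tm_classes <- c("TM", "SP+TM", "BETA", "SP+BETA")
  tibble::tibble(
    protein_id = ids,
    predicted_class = classes,
    tmr_count = ifelse(classes %in% tm_classes, 1L, 0L),
    has_signal_peptide = startsWith(classes, "SP"),
    has_outside_region = outside,
    length = NA_integer_,
    sequence = NA_character_,
    segments = replicate(length(ids),
                         tibble::tibble(start = integer(0), end = integer(0),
                                        label = character(0)),
                         simplify = FALSE)
  )
}

# Detection profiles built directly from BX/BY/BU counts.
profiles_from_counts <- function(ids, bx, by, bu = 0L) {
  out <- tibble::tibble(
    protein_id = rep(ids, each = 3L),
    condition = rep(c("BU", "BX", "BY"), length(ids)),
    n_replicates = 3L,
    n_detected = as.integer(rbind(bu, bx, by))
  )
  out$detected <- out$n_detected >= 1L
  class(out) <- c("detection_profiles", class(out))
  out
}
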