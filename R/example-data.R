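# Worked-example data: the bovine X-sperm candidate set. Nineteen sperm
# surface-accessible proteins detected in at least one X-sorted (BX)
# replicate and in no Y-sorted (BY) replicate, with their predicted topology
# class and BX replicate counts. Used as a self-contained fixture for the
# rule engine: seven rows carry a transmembrane topology class, and five of
# those were seen in two or three BX replicates — the prioritized candidates
# ADAM2, ATP11C, PMCA4 (ATP2B4), DSG1 and MCT1 (SLC16A1).

#' Bovine X-sperm surface-candidate example table
#'
#' A bundled worked example: nineteen bovine sperm proteins possibly
#' accessible from the cell surface, identified in at least one X-sorted (BX)
#' replicate and in no Y-sorted (BY) replicate, together with their predicted
#' membrane topology class and the number of BX replicates in which each was
#' identified. Transmembrane rows are recorded with one membrane region (the
#' minimum their class implies). Since GO evidence underlies each row's
#' surface-accessible status, every row carries the cell-surface category in
#' the encoded inputs of [candidate_example_inputs()].
#'
#' @return A tibble with columns `protein_id`, `chromosome`, `gene`,
#'   `topology_class`, `bx_replicates`.
#' @export
#' @examples
#' candidate_example_table()
candidate_example_table <- function() {
  tibble::tribble(
    ~protein_id,  ~chromosome, ~gene,      ~topology_class, ~bx_replicates,
    "A0A3Q1LK79", "17",        "Adam1b",   "SP",            2L,
    "O77780",     "Unplaced",  "ADAM2",    "SP+TM",         3L,
    "P09487",     "2",         "ALPL",     "SP",            1L,
    "F1N3G6",     "X",         "ATP11C",   "TM",            2L,
    "Q3T0C6",     "1",         "ATP1B3",   "TM",            1L,
    "D3K0R6",     "16",        "ATP2B4",   "TM",            2L,
    "P00829",     "Unplaced",  "ATP5F1B",  "GLOB",          2L,
    "Q03763",     "Unplaced",  "DSG1",     "SP+TM",         2L,
    "Q32LB5",     "5",         "GLIPR1L1", "SP",            3L,
    "Q27975",     "23",        "HSPA1A",   "GLOB",          2L,
    "P0CB32",     "23",        "HSPA1L",   "GLOB",          2L,
    "P34933",     "Unplaced",  "HSPA2",    "GLOB",          2L,
    "Q0VCX2",     "11",        "HSPA5",    "SP",            2L,
    "P19120",     "15",        "HSPA8",    "GLOB",          2L,
    "P31081",     "22",        "HSPD1",    "GLOB",          3L,
    "Q3MHW6",     "3",         "SLC16A1",  "TM",            3L,
    "Q32PB3",     "18",        "SPACA4",   "SP",            2L,
    "F1MTV1",     "4",         "SPAM1",    "SP",            2L,
    "A0A3Q1MQE3", "Unplaced",  NA,         "SP+TM",         1L
  )
}

#' Encode the example table as rule-engine inputs
#'
#' Turns [candidate_example_table()] into the three inputs of
#' [call_targets()]: detection profiles (BX counts as printed, BY all zero),
#' interest calls (every row is surface-annotated: the table lists the
#' surface-accessible set, encoded as the cell-surface category `CS`), and
#' topology records (class as printed; transmembrane classes with one
#' membrane region).
#'
#' @return A list with elements `profiles`, `interest`, `topo`.
#' @export
#' @examples
#' inp <- candidate_example_inputs()
#' calls <- call_targets(inp$profiles, inp$interest, inp$topo)
#' table(calls$tier)
candidate_example_inputs <- function() {
  tab <- candidate_example_table()
  profiles <- tab %>%
    dplyr::select("protein_id", BX = "bx_replicates") %>%
    dplyr::mutate(BY = 0L, BU = 0L) %>%
    tidyr::pivot_longer(c("BX", "BY", "BU"), names_to = "condition",
                        values_to = "n_detected") %>%
    dplyr::mutate(n_replicates = 3L, detected = .data$n_detected >= 1L) %>%
    dplyr::select("protein_id", "condition", "n_replicates", "n_detected",
                  "detected")
  class(profiles) <- c("detection_profiles", class(profiles))

  cs_id <- GO_INTEREST$go_id[GO_INTEREST$category == "CS"][1]
  interest <- tibble::tibble(
    protein_id = tab$protein_id,
    unique_protein_id = tab$protein_id,
    gene = tab$gene,
    chromosome = tab$chromosome,
    go_union = lapply(seq_len(nrow(tab)), function(i) cs_id)
  ) %>% classify_interest()

  tm_classes <- c("TM", "SP+TM", "BETA", "SP+BETA")
  topo <- tibble::tibble(
    protein_id = tab$protein_id,
    predicted_class = tab$topology_class,
    tmr_count = ifelse(tab$topology_class %in% tm_classes, 1L, 0L),
    has_signal_peptide = startsWith(tab$topology_class, "SP"),
    has_outside_region = tab$topology_class != "GLOB",
    length = NA_integer_,
    sequence = NA_character_,
    segments = replicate(nrow(tab), tibble::tibble(start = integer(0),
                                                   end = integer(0),
                                                   label = character(0)),
                         simplify = FALSE)
  )
  list(profiles = profiles, interest = interest, topo = topo)
}
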