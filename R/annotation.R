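# Protein annotation: pick one representative ID per protein group, merge GO
# identifiers from the UniProt-style and eggNOG-style sources, and classify
# proteins against the fourteen GO identifiers of interest.

#' Read a UniProt-style annotation table
#'
#' TSV with columns `id`, `reviewed` (logical), `gene`, `chromosome`,
#' `go_ids` (semicolon-separated GO identifiers, possibly empty).
#'
#' @param path Path to the TSV, or a data frame with the same columns.
#' @return A tibble with `go_ids` parsed into a list-column `go`.
#' @export
read_uniprot_annotation <- function(path) {
  tab <- if (is.data.frame(path)) tibble::as_tibble(path) else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
  missing <- setdiff(c("id", "reviewed", "gene", "chromosome", "go_ids"),
                     names(tab))
  if (length(missing) > 0) {
    abort_format(paste0("uniprot annotation lacks column '", missing[1], "'"))
  }
  tab$reviewed <- as.logical(tab$reviewed)
  tab$go <- split_go_ids(tab$go_ids)
  tab
}

#' Read an eggNOG-style annotation table
#'
#' TSV with columns `id` and `go_ids` (semicolon-separated).
#'
#' @param path Path to the TSV, or a data frame with the same columns.
#' @return A tibble with a `go` list-column.
#' @export
read_eggnog_annotation <- function(path) {
  tab <- if (is.data.frame(path)) tibble::as_tibble(path) else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
  missing <- setdiff(c("id", "go_ids"), names(tab))
  if (length(missing) > 0) {
    abort_format(paste0("eggnog annotation lacks column '", missing[1], "'"))
  }
  tab$go <- split_go_ids(tab$go_ids)
  tab
}

split_go_ids <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Select the representative protein ID of a group
#'
#' The unique protein ID of a group is the first reviewed entry of the
#' majority-ID list, or the first entry if none is reviewed.
#'
#' @param majority_ids Character vector of majority protein IDs, in order.
#' @param reviewed_flags Logical vector of the same length (`NA` = unreviewed).
#' @return A single protein ID.
#' @export
#' @examples
#' select_unique_id(c("A", "B", "C"), c(FALSE, TRUE, TRUE))  # "B"
select_unique_id <- function(majority_ids, reviewed_flags) {
  if (length(majority_ids) == 0L) {
    abort_value("majority-ID list is empty")
  }
  reviewed_flags <- reviewed_flags & !is.na(reviewed_flags)
  if (any(reviewed_flags)) {
    majority_ids[which(reviewed_flags)[1]]
  } else {
    majority_ids[1]
  }
}

#' Merge GO annotation from two sources
#'
#' Set union of the UniProt-derived and eggNOG-derived GO identifiers of a
#' protein. Every identifier must be syntactically valid (`GO:` followed by
#' seven digits).
#'
#' @param uniprot_set,eggnog_set Character vectors of GO identifiers.
#' @return Character vector of the union, duplicates collapsed, sorted.
#' @export
merge_go <- function(uniprot_set, eggnog_set) {
  all_ids <- c(uniprot_set, eggnog_set)
  bad <- all_ids[!is_valid_go_id(all_ids)]
  if (length(bad) > 0) {
    abort_format(paste0("malformed GO identifier: '", bad[1], "'"))
  }
  sort(unique(all_ids))
}

#' Annotate protein groups
#'
#' For every protein group (a `;`-separated majority-ID string), selects the
#' unique protein ID with [select_unique_id()] using the reviewed flags of the
#' UniProt source, then joins the gene name, chromosome and the GO sets of
#' both sources keyed on that unique ID, and forms the GO union. IDs missing
#' from a source contribute an empty set for that source.
#'
#' @param protein_ids Character vector of majority-ID strings.
#' @param uniprot A [read_uniprot_annotation()] tibble.
#' @param eggnog A [read_eggnog_annotation()] tibble.
#' @return A tibble with columns `protein_id`, `unique_protein_id`,
#'   `reviewed`, `gene`, `chromosome` and list-columns `go_uniprot`,
#'   `go_eggnog`, `go_union`.
#' @export
annotate_proteins <- function(protein_ids, uniprot, eggnog) {
  uni_idx <- setNames(seq_len(nrow(uniprot)), uniprot$id)
  egg_idx <- setNames(seq_len(nrow(eggnog)), eggnog$id)
  recs <- purrr::map(protein_ids, function(group) {
    ids <- trimws(strsplit(group, ";", fixed = TRUE)[[1]])
    flags <- uniprot$reviewed[uni_idx[ids]]
    uid <- select_unique_id(ids, flags)
    ui <- unname(uni_idx[uid])
    ei <- unname(egg_idx[uid])
    go_u <- if (!is.na(ui)) uniprot$go[[ui]] else character(0)
    go_e <- if (!is.na(ei)) eggnog$go[[ei]] else character(0)
    tibble::tibble(
      protein_id = group,
      unique_protein_id = uid,
      reviewed = if (!is.na(ui)) isTRUE(uniprot$reviewed[ui]) else FALSE,
      gene = if (!is.na(ui)) uniprot$gene[ui] else NA_character_,
      chromosome = if (!is.na(ui)) uniprot$chromosome[ui] else NA_character_,
      go_uniprot = list(go_u),
      go_eggnog = list(go_e),
      go_union = list(merge_go(go_u, go_e))
    )
  })
  dplyr::bind_rows(recs)
}

#' Classify proteins against the GO identifiers of interest
#'
#' Matches each protein's GO union against the fourteen fixed identifiers
#' (see [go_interest_terms()]) and records the category codes hit. A protein
#' is "of interest" when it hits any plasma-membrane/cell-surface category
#' (`PM`, `CS`, `ESPM`, `ECESPM`, `ACPM`, `ACESPM`, `ICESPM`, `ICPM`, `ESCW`,
#' `ESCOM`); a protein whose only hit is extracellular space (`ES`) is of
#' interest only if it is transmembrane, which is resolved downstream when
#' topology is joined (see [call_targets()]) and reported here as
#' `interest_es_pending`.
#'
#' @param annotations An [annotate_proteins()] tibble (needs `protein_id` and
#'   the `go_union` list-column).
#' @return The tibble with list-column `categories` and logical columns
#'   `of_interest` (direct rule only) and `interest_es_pending` added.
#' @export
classify_interest <- function(annotations) {
  cat_of <- setNames(GO_INTEREST$category, GO_INTEREST$go_id)
  out <- annotations
  out$categories <- lapply(annotations$go_union, function(gos) {
    unique(unname(cat_of[gos[gos %in% names(cat_of)]]))
  })
  direct <- vapply(out$categories, function(cc) {
    any(cc %in% GO_CATEGORIES_DIRECT)
  }, logical(1))
  has_es <- vapply(out$categories, function(cc) "ES" %in% cc, logical(1))
  out$of_interest <- direct
  out$interest_es_pending <- has_es & !direct
  class(out) <- unique(c("interest_calls", class(out)))
  out
}
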