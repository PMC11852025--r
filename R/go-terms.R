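# The fixed list of GO identifiers used to flag plasma-membrane / cell-surface
# / extracellular localization. IDs are matched literally (no ontology
# traversal): the interest rule works on these exact identifiers, including
# GO:0005887 which newer ontology releases merge into GO:0005886.

GO_INTEREST <- tibble::tibble(
  go_id = c(
    "GO:0005886", "GO:0005904",               # plasma membrane
    "GO:0009986", "GO:0009928", "GO:0009929", # cell surface
    "GO:0009897",                             # external side of plasma membrane
    "GO:0031232",                             # extrinsic component of ext. side of PM
    "GO:0046658",                             # anchored component of PM
    "GO:0031362",                             # anchored component of ext. side of PM
    "GO:0071575",                             # integral component of ext. side of PM
    "GO:0005887",                             # integral component of PM
    "GO:0010339",                             # external side of cell wall
    "GO:0031240",                             # external side of cell outer membrane
    "GO:0005615"                              # extracellular space
  ),
  category = c(
    "PM", "PM",
    "CS", "CS", "CS",
    "ESPM",
    "ECESPM",
    "ACPM",
    "ACESPM",
    "ICESPM",
    "ICPM",
    "ESCW",
    "ESCOM",
    "ES"
  )
)

# Category groups driving the interest / accessibility rules:
# - every category except ES marks a protein "of interest" outright;
# - CS-group categories are surface-accessible regardless of topology;
# - PM-group categories need transmembrane topology or an outside segment;
# - ES needs transmembrane topology (both for interest and accessibility).
GO_CATEGORIES_DIRECT <- c(
  "PM", "CS", "ESPM", "ECESPM", "ACPM", "ACESPM", "ICESPM", "ICPM",
  "ESCW", "ESCOM"
)
GO_CATEGORIES_ACCESS_ALWAYS <- c(
  "CS", "ESPM", "ECESPM", "ACESPM", "ICESPM", "ESCW", "ESCOM"
)
GO_CATEGORIES_ACCESS_PM <- c("PM", "ACPM", "ICPM")

#' GO identifiers of interest for cell-surface localization
#'
#' The fourteen Gene Ontology identifiers, related to the plasma membrane,
#' cell surface and extracellular space, that the marker-selection rules match
#' literally against each protein's merged GO annotation. Each ID carries a
#' category code (`PM`, `CS`, `ESPM`, `ECESPM`, `ACPM`, `ACESPM`, `ICESPM`,
#' `ICPM`, `ESCW`, `ESCOM`, `ES`) that determines how it enters the
#' of-interest and surface-accessibility rules (see [classify_interest()] and
#' [surface_accessible()]).
#'
#' @return A tibble with columns `go_id` and `category`.
#' @export
#' @examples
#' go_interest_terms()
go_interest_terms <- function() {
  GO_INTEREST
}

is_valid_go_id <- function(x) {
  grepl("^GO:[0-9]{7}$", x)
}
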