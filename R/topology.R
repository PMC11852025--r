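# Topology-prediction parsing: 3line dialect and a tabular summary dialect.
# Coordinates are 1-based inclusive. Per-residue codes: S signal, I inside,
# O outside, M alpha-helical membrane, B beta strand.

TOPOLOGY_CLASSES <- c("TM", "SP+TM", "GLOB", "SP", "BETA", "SP+BETA")
TOPOLOGY_LABELS <- c(S = "signal", I = "inside", O = "outside",
                     M = "TMhelix", B = "Beta")

empty_topology_records <- function() {
  tibble::tibble(
    protein_id = character(0), predicted_class = character(0),
    tmr_count = integer(0), has_signal_peptide = logical(0),
    has_outside_region = logical(0), length = integer(0),
    sequence = character(0), segments = list()
  )
}

segments_from_string <- function(topo) {
  r <- rle(strsplit(topo, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- setdiff(unique(r$values), names(TOPOLOGY_LABELS))
  if (length(bad) > 0) {
    abort_format(paste0("unknown topology code '", bad[1], "'"))
  }
  tibble::tibble(start = starts, end = ends,
                 label = unname(TOPOLOGY_LABELS[r$values]))
}

string_from_segments <- function(segments) {
  codes <- setNames(names(TOPOLOGY_LABELS), TOPOLOGY_LABELS)
  paste(unlist(Map(function(s, e, l) strrep(codes[[l]], e - s + 1L),
                   segments$start, segments$end, segments$label)),
        collapse = "")
}

membrane_label_for_class <- function(class) {
  if (class %in% c("BETA", "SP+BETA")) "Beta" else "TMhelix"
}

count_tmr <- function(segments, class) {
  sum(segments$label == membrane_label_for_class(class))
}

validate_topology_record <- function(id, class, segments, seq_len = NULL) {
  if (!class %in% TOPOLOGY_CLASSES) {
    abort_format(paste0("unknown topology class '", class, "' for ", id))
  }
  if (nrow(segments) > 0) {
    if (segments$start[1] != 1L ||
        any(segments$start[-1] != segments$end[-nrow(segments)] + 1L)) {
      abort_validation(paste0("segments of ", id, " do not tile the sequence"))
    }
    if (!is.null(seq_len) && segments$end[nrow(segments)] != seq_len) {
      abort_format(paste0("topology string length differs from sequence length for ", id))
    }
  }
  tmr <- count_tmr(segments, class)
  has_sp <- any(segments$label == "signal")
  if (has_sp != startsWith(class, "SP")) {
    abort_validation(paste0("signal-peptide segments inconsistent with class '",
                            class, "' for ", id))
  }
  if (class %in% c("TM", "SP+TM", "BETA", "SP+BETA") && tmr < 1) {
    abort_validation(paste0("class '", class, "' requires >= 1 membrane region (", id, ")"))
  }
  if (class %in% c("GLOB", "SP") &&
      sum(segments$label %in% c("TMhelix", "Beta")) > 0) {
    abort_validation(paste0("class '", class, "' must have no membrane regions (", id, ")"))
  }
  invisible(tmr)
}

topology_records_from_strings <- function(ids, classes, sequences, topo_strings) {
  recs <- purrr::pmap(
    list(ids, classes, sequences, topo_strings),
    function(id, class, seq, topo) {
      if (nchar(topo) != nchar(seq)) {
        abort_format(paste0("topology string length (", nchar(topo),
                            ") differs from sequence length (", nchar(seq),
                            ") for ", id))
      }
      segments <- segments_from_string(topo)
      tmr <- validate_topology_record(id, class, segments, nchar(seq))
      tibble::tibble(
        protein_id = id, predicted_class = class, tmr_count = as.integer(tmr),
        has_signal_peptide = any(segments$label == "signal"),
        has_outside_region = any(segments$label == "outside"),
        length = nchar(seq), sequence = seq, segments = list(segments)
      )
    }
  )
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) empty_topology_records() else out
}

#' Parse topology predictions in 3line format
#'
#' Reads the three-line-per-protein dialect emitted by deep-learning topology
#' predictors: a header `><id> | <class>`, the amino-acid sequence, and a
#' per-residue topology string over the codes `S` (signal peptide), `I`
#' (inside), `O` (outside), `M` (alpha-helical membrane) and `B` (beta
#' strand). Segments are reconstructed by run-length encoding; the class is
#' taken from the header and checked against the segments (no silent repair).
#'
#' @param path Path to a 3line file.
#' @return A tibble of topology records: `protein_id`, `predicted_class` (one
#'   of `TM`, `SP+TM`, `GLOB`, `SP`, `BETA`, `SP+BETA`), `tmr_count`,
#'   `has_signal_peptide`, `has_outside_region`, `length`, `sequence` and a
#'   `segments` list-column of `(start, end, label)` tibbles with 1-based
#'   inclusive coordinates.
#' @export
parse_3line <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_topology_records())
  if (length(lines) %% 3L != 0L) {
    abort_format("3line file must contain header/sequence/topology triplets")
  }
  heads <- lines[seq(1, length(lines), by = 3)]
  seqs <- lines[seq(2, length(lines), by = 3)]
  topos <- lines[seq(3, length(lines), by = 3)]
  m <- regmatches(heads, regexec("^>\\s*(\\S+)\\s*\\|\\s*(\\S+)\\s*$", heads))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort_format(paste0("malformed 3line header: '", heads[bad][1], "'"))
  }
  ids <- vapply(m, `[`, character(1), 2)
  classes <- vapply(m, `[`, character(1), 3)
  topology_records_from_strings(ids, classes, seqs, topos)
}

#' Write topology records in 3line format
#'
#' Inverse of [parse_3line()]: emits one header/sequence/topology triplet per
#' record, so that `parse_3line(write_3line(x, path))` round-trips.
#'
#' @param records Topology records as returned by [parse_3line()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_3line <- function(records, path) {
  lines <- unlist(purrr::pmap(
    list(records$protein_id, records$predicted_class, records$sequence,
         records$segments),
    function(id, class, seq, segments) {
      c(paste0(">", id, " | ", class), seq, string_from_segments(segments))
    }
  ))
  writeLines(lines %||% character(0), path)
  invisible(path)
}

#' Parse a tabular topology summary
#'
#' Reads a TSV dialect with columns `id`, `class`, `tmr_count` and an optional
#' `segments` column (entries like `"signal:1-15;outside:16-40"`). Rows whose
#' class and region count are inconsistent (e.g. a globular protein with a
#' membrane region) raise a validation error. Segmentless rows have an
#' unknown outside-region status, which is conservatively recorded as `FALSE`
#' with a warning.
#'
#' @param path Path to a TSV file, or a data frame with the same columns.
#' @return A tibble of topology records (see [parse_3line()]; `sequence` is
#'   `NA` and `segments` may be empty).
#' @export
parse_topology_table <- function(path) {
  tab <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  if (nrow(tab) == 0L) return(empty_topology_records())
  required <- c("id", "class", "tmr_count")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort_format(paste0("topology table lacks required column '", missing[1], "'"))
  }
  has_segments <- "segments" %in% names(tab)
  warned <- FALSE
  recs <- purrr::pmap(
    list(tab$id, tab$class, as.integer(tab$tmr_count),
         if (has_segments) tab$segments else rep(NA_character_, nrow(tab))),
    function(id, class, tmr, segstr) {
      if (!class %in% TOPOLOGY_CLASSES) {
        abort_format(paste0("unknown topology class '", class, "' for ", id))
      }
      if (is.na(tmr) || tmr < 0) {
        abort_validation(paste0("invalid tmr_count for ", id))
      }
      if (class %in% c("GLOB", "SP") && tmr != 0) {
        abort_validation(paste0("class '", class, "' with tmr_count ", tmr,
                                " is inconsistent (", id, ")"))
      }
      if (class %in% c("TM", "SP+TM", "BETA", "SP+BETA") && tmr < 1) {
        abort_validation(paste0("class '", class, "' with tmr_count ", tmr,
                                " is inconsistent (", id, ")"))
      }
      if (!is.na(segstr) && nzchar(segstr)) {
        segments <- parse_segment_string(segstr, id)
        validate_topology_record(id, class, segments)
        if (count_tmr(segments, class) != tmr) {
          abort_validation(paste0("tmr_count disagrees with segments for ", id))
        }
        has_out <- any(segments$label == "outside")
      } else {
        segments <- tibble::tibble(start = integer(0), end = integer(0),
                                   label = character(0))
        if (!warned) {
          rlang::warn("segmentless topology rows: outside-region status unknown, recorded as FALSE")
          warned <<- TRUE
        }
        has_out <- FALSE
      }
      tibble::tibble(
        protein_id = id, predicted_class = class, tmr_count = tmr,
        has_signal_peptide = startsWith(class, "SP"),
        has_outside_region = has_out,
        length = if (nrow(segments) > 0) max(segments$end) else NA_integer_,
        sequence = NA_character_, segments = list(segments)
      )
    }
  )
  dplyr::bind_rows(recs)
}

parse_segment_string <- function(x, id) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(signal|inside|outside|TMhelix|Beta):([0-9]+)-([0-9]+)$", parts))
  if (any(vapply(m, length, integer(1)) != 4L)) {
    abort_format(paste0("malformed segment string for ", id, ": '", x, "'"))
  }
  tibble::tibble(
    start = as.integer(vapply(m, `[`, character(1), 3)),
    end = as.integer(vapply(m, `[`, character(1), 4)),
    label = vapply(m, `[`, character(1), 2)
  )
}

#' Transmembrane status of topology records
#'
#' A protein counts as transmembrane when its predicted class is membrane-
#' embedded (`TM`, `SP+TM`, `BETA` or `SP+BETA`) and it has at least one
#' membrane region. Signal-peptide-only and globular proteins are not
#' transmembrane.
#'
#' @param records Topology records (see [parse_3line()]).
#' @return Logical vector, one element per record.
#' @export
is_transmembrane <- function(records) {
  records$predicted_class %in% c("TM", "SP+TM", "BETA", "SP+BETA") &
    records$tmr_count >= 1L
}
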