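#' Read a FASTA file into a tibble
#'
#' Parses a (possibly multi-record) FASTA file of DNA sequences. Sequences
#' are upper-cased, whitespace is stripped, and record order is preserved.
#' The record id is the first whitespace-delimited token of the header; the
#' full header is kept in `desc`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence` and `desc`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "darktaxa_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  non_blank <- which(nzchar(trimws(lines)))
  if (length(non_blank) == 0L) {
    abort(paste0("empty FASTA file: ", path), class = "darktaxa_format_error")
  }
  first <- non_blank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(
      paste0("malformed FASTA: line ", first, " is not a header in ", path),
      class = "darktaxa_format_error"
    )
  }
  hdr <- startsWith(trimws(lines), ">")
  grp <- cumsum(hdr)
  headers <- trimws(lines[hdr])
  desc <- sub("^>", "", headers)
  ids <- vapply(strsplit(desc, "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    bad <- which(hdr)[!nzchar(sub("^>", "", headers))][1L]
    abort(
      paste0("malformed FASTA: empty header at line ", bad, " in ", path),
      class = "darktaxa_format_error"
    )
  }
  seqs <- vapply(
    split(lines[!hdr & seq_along(lines) >= first], grp[!hdr & seq_along(lines) >= first]),
    function(x) toupper(gsub("\\s", "", paste(x, collapse = ""))),
    character(1)
  )
  out <- tibble(
    id = ids,
    sequence = unname(seqs[as.character(seq_along(ids))]),
    desc = desc
  )
  out$sequence[is.na(out$sequence)] <- ""
  if (any(!nzchar(out$sequence))) {
    abort(
      paste0(
        "malformed FASTA: record(s) with empty sequence: ",
        paste(out$id[!nzchar(out$sequence)], collapse = ", ")
      ),
      class = "darktaxa_format_error"
    )
  }
  dup <- unique(out$id[duplicated(out$id)])
  if (length(dup)) {
    abort(
      paste0("duplicate FASTA ids: ", paste(dup, collapse = ", ")),
      class = "darktaxa_format_error"
    )
  }
  check_dna(out$sequence, out$id)
  out
}

iupac_chars <- c(
  "A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"
)

check_dna <- function(seqs, ids) {
  ok <- !grepl(paste0("[^", paste(iupac_chars, collapse = ""), "]"), seqs)
  if (any(!ok)) {
    abort(
      paste0(
        "non-IUPAC characters in sequence(s): ",
        paste(ids[!ok], collapse = ", ")
      ),
      class = "darktaxa_format_error"
    )
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param x A data frame with columns `id` and `sequence` (an optional
#'   `desc` column is written as the header when present).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `x`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  hdr <- if ("desc" %in% names(x) && !all(x$desc == x$id)) x$desc else x$id
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", hdr[i]), con)
    s <- x$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(x)
}

site_numeric_cols <- c("MAT", "MAP", "pH", "soil_C", "soil_P", "fire_time")
site_required_cols <- c("sample_id", site_numeric_cols, "biome", "region")

#' Read a site metadata table
#'
#' Reads a tab-delimited site metadata table with the six environmental
#' predictors (`MAT` degC, `MAP` mm/yr, `pH`, `soil_C` %, `soil_P` mg/kg,
#' `fire_time` yr) plus `biome` and `region` labels. Unparseable numeric
#' cells become `NA` and their count is reported with a message. Values
#' violating hard physical invariants (pH outside \[0, 14\], negative MAP or
#' fire_time) raise an error.
#'
#' @param path Path to a TSV file with a header row; `"NA"` marks missing.
#' @return A tibble with one row per site.
#' @export
read_site_table <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(site_required_cols, names(raw))
  if (length(missing_cols)) {
    abort(
      paste0(
        "site table is missing mandatory column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "darktaxa_format_error"
    )
  }
  n_bad <- 0L
  for (col in site_numeric_cols) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & v != "NA" & is.na(num)
    n_bad <- n_bad + sum(bad)
    raw[[col]] <- num
  }
  if (n_bad > 0L) {
    message(n_bad, " unparseable numeric cell(s) set to NA in ", path)
  }
  validate_sites(raw)
  raw
}

validate_sites <- function(sites) {
  bad_ph <- !is.na(sites$pH) & (sites$pH < 0 | sites$pH > 14)
  if (any(bad_ph)) {
    abort(
      paste0(
        "pH outside [0, 14] for sample(s): ",
        paste(sites$sample_id[bad_ph], collapse = ", ")
      ),
      class = "darktaxa_validation_error"
    )
  }
  for (col in c("MAP", "fire_time")) {
    bad <- !is.na(sites[[col]]) & sites[[col]] < 0
    if (any(bad)) {
      abort(
        paste0(
          col, " negative for sample(s): ",
          paste(sites$sample_id[bad], collapse = ", ")
        ),
        class = "darktaxa_validation_error"
      )
    }
  }
  invisible(sites)
}

#' Write a site metadata table
#' @param sites A site metadata tibble (see [read_site_table()]).
#' @param path Output TSV path.
#' @return `sites`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites, path, na = "NA")
  invisible(sites)
}

#' Read / write a site-by-OTU occurrence table
#'
#' Occurrences are stored long: one row per `(sample_id, otu_id)` pair with
#' a non-negative `occurrence` value (binary presence or a count/weight).
#'
#' @param path TSV path.
#' @return A tibble with columns `sample_id`, `otu_id`, `occurrence`.
#' @export
read_occurrence_table <- function(path) {
  occ <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      otu_id = readr::col_character(),
      occurrence = readr::col_double()
    ),
    progress = FALSE
  )
  if (any(occ$occurrence < 0, na.rm = TRUE)) {
    abort("negative occurrence values", class = "darktaxa_validation_error")
  }
  occ
}

#' @rdname read_occurrence_table
#' @param occ Occurrence tibble.
#' @export
write_occurrence_table <- function(occ, path) {
  readr::write_tsv(occ, path, na = "NA")
  invisible(occ)
}

primer_table_cols <- c(
  "target_id", "direction", "primer_seq", "length", "Tm", "GC_pct",
  "three_prime_hits", "distance_to_flank", "universal_partner",
  "amplified_gene"
)

#' Write a primer table
#'
#' Writes primer pairs as a TSV with one row per (specific primer,
#' universal partner) combination — the machine-readable analogue of a
#' published primer supplement.
#'
#' @param pairs A tibble of primer pairs as returned by
#'   [pair_with_universal()] (columns `target_id`, `direction`,
#'   `primer_seq`, `length`, `Tm`, `GC_pct`, `three_prime_hits`,
#'   `distance_to_flank`, `universal_partner`, `amplified_gene`).
#' @param path Output TSV path.
#' @return `pairs`, invisibly.
#' @export
write_primer_table <- function(pairs, path) {
  if (nrow(pairs) == 0L) {
    empty <- as_tibble(setNames(
      rep(list(character(0)), length(primer_table_cols)), primer_table_cols
    ))
    readr::write_tsv(empty, path)
    return(invisible(pairs))
  }
  stopifnot(all(primer_table_cols %in% names(pairs)))
  readr::write_tsv(pairs[, primer_table_cols], path, na = "NA")
  invisible(pairs)
}

#' @rdname write_primer_table
#' @export
read_primer_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      target_id = readr::col_character(),
      direction = readr::col_character(),
      primer_seq = readr::col_character(),
      length = readr::col_integer(),
      Tm = readr::col_double(),
      GC_pct = readr::col_double(),
      three_prime_hits = readr::col_integer(),
      distance_to_flank = readr::col_integer(),
      universal_partner = readr::col_character(),
      amplified_gene = readr::col_character()
    ),
    progress = FALSE
  )
}
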