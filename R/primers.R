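#' Primer design criteria and conditions
#'
#' Bounds for the five design criteria applied to every candidate
#' oligo — melting temperature 54-58 degC, GC content 33-62%, length
#' 16-21 bases, exact 3'-decamer matches in fewer than 20 OTUs of the
#' whole data set, and more than 20 bases distance from both flanking
#' conserved-gene boundaries — plus the melting-temperature model and its
#' solution conditions. All bounds are configurable.
#'
#' @param tm_min,tm_max Melting temperature window in degC.
#' @param gc_min,gc_max GC content window in percent.
#' @param len_min,len_max Primer length window in bases.
#' @param specificity_max Pass iff the 3'-decamer hits strictly fewer
#'   than this many OTUs. Default 20.
#' @param flank_min Pass iff the candidate lies strictly more than this
#'   many bases from both variable-window boundaries. Default 20.
#' @param tm_method,oligo_uM,na_mM Passed to [melting_temperature()].
#' @param max_product Maximum in-silico PCR product length in bases.
#' @return A list of class `primer_config`.
#' @export
primer_config <- function(tm_min = 54, tm_max = 58,
                          gc_min = 33, gc_max = 62,
                          len_min = 16L, len_max = 21L,
                          specificity_max = 20L,
                          flank_min = 20L,
                          tm_method = "nearest_neighbor",
                          oligo_uM = 0.5, na_mM = 50,
                          max_product = 3000L) {
  stopifnot(
    tm_min <= tm_max, gc_min <= gc_max, len_min <= len_max,
    len_min >= 10L, specificity_max >= 1L, flank_min >= 0L
  )
  structure(
    list(
      tm_min = tm_min, tm_max = tm_max, gc_min = gc_min, gc_max = gc_max,
      len_min = as.integer(len_min), len_max = as.integer(len_max),
      specificity_max = as.integer(specificity_max),
      flank_min = as.integer(flank_min),
      tm_method = tm_method, oligo_uM = oligo_uM, na_mM = na_mM,
      max_product = as.integer(max_product)
    ),
    class = "primer_config"
  )
}

#' Count OTUs exactly containing a primer's 3' decamer
#'
#' The mis-priming proxy: for each candidate, the number of OTUs whose
#' sequence contains the candidate's 3'-terminal 10-mer as an exact
#' substring on either strand (primers act on double-stranded templates).
#' The candidate's own target counts.
#'
#' @param candidates Character vector of candidate primer sequences
#'   (length >= 10 each).
#' @param otus Tibble with columns `otu_id` and `sequence`.
#' @return Integer vector of OTU hit counts, one per candidate.
#' @export
three_prime_specificity <- function(candidates, otus) {
  if (any(nchar(candidates) < 10L)) {
    abort("candidates must be at least 10 bases long",
      class = "darktaxa_validation_error"
    )
  }
  # both strands of every OTU, joined with an unmatchable spacer
  haystack <- paste(
    toupper(otus$sequence), reverse_complement(otus$sequence),
    sep = "----"
  )
  decamers <- substr(candidates, nchar(candidates) - 9L, nchar(candidates))
  counts <- vapply(
    unique(decamers),
    function(d) sum(stringr::str_detect(haystack, stringr::fixed(d))),
    integer(1)
  )
  unname(counts[decamers])
}

#' Evaluate the five primer criteria for located candidates
#'
#' @param candidates Tibble with columns `sequence`, `direction`
#'   (`"forward"`/`"reverse"`), `template_start`, `template_end` (0-based
#'   half-open coordinates on the target template).
#' @param otus OTU data set against which 3'-decamer specificity is
#'   counted.
#' @param window Integer vector `c(start, end)`: the annotated variable
#'   region (0-based half-open); candidates outside it are an error. Its
#'   boundaries are the flanking conserved-gene junctions used for the
#'   flank-distance criterion.
#' @param config A [primer_config()].
#' @return `candidates` with measured values (`length`, `Tm`, `GC_pct`,
#'   `three_prime_hits`, `distance_to_flank`) and per-criterion logicals
#'   (`pass_tm`, `pass_gc`, `pass_length`, `pass_specificity`,
#'   `pass_flank`, and overall `pass`).
#' @export
evaluate_criteria <- function(candidates, otus, window,
                              config = primer_config()) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (any(candidates$template_start < window[1] |
    candidates$template_end > window[2])) {
    abort("candidate outside the annotated variable region",
      class = "darktaxa_validation_error"
    )
  }
  out <- candidates |>
    mutate(
      length = nchar(.data$sequence),
      Tm = melting_temperature(
        .data$sequence,
        method = config$tm_method,
        oligo_uM = config$oligo_uM, na_mM = config$na_mM
      ),
      GC_pct = 100 * gc_fraction(.data$sequence),
      three_prime_hits = three_prime_specificity(.data$sequence, otus),
      dist_5p = .data$template_start - window[1],
      dist_3p = window[2] - .data$template_end,
      distance_to_flank = pmin(.data$dist_5p, .data$dist_3p)
    ) |>
    mutate(
      pass_tm = .data$Tm >= config$tm_min & .data$Tm <= config$tm_max,
      pass_gc = .data$GC_pct >= config$gc_min & .data$GC_pct <= config$gc_max,
      pass_length = .data$length >= config$len_min &
        .data$length <= config$len_max,
      pass_specificity = .data$three_prime_hits < config$specificity_max,
      pass_flank = .data$distance_to_flank > config$flank_min,
      pass = .data$pass_tm & .data$pass_gc & .data$pass_length &
        .data$pass_specificity & .data$pass_flank
    )
  out
}

#' Design taxon-specific primers in a variable window
#'
#' Enumerates every substring of length `len_min`-`len_max` of the
#' variable window as a forward candidate and its reverse complement as a
#' reverse candidate, evaluates the five criteria against the whole OTU
#' data set, and returns the passing candidates ranked by (fewest
#' 3'-decamer hits, then Tm closest to 56 degC, then longer length, then
#' 5' position). For a grouped target (several member sequences), a
#' candidate is only eligible if the underlying template slice is
#' sequence-identical across all members, so one oligo serves the whole
#' group.
#'
#' @param target Character vector of one or more member template
#'   sequences (equal lengths; the synthetic generator's substitution-only
#'   model guarantees a shared coordinate map).
#' @param otus OTU data set for the specificity criterion.
#' @param window `c(start, end)` 0-based half-open variable region;
#'   defaults to the whole template.
#' @param config A [primer_config()].
#' @param target_id Label attached to the output. Default `"target"`.
#' @return A tibble of passing candidates with criterion metrics,
#'   `direction` and within-direction `rank`.
#' @export
design_primers <- function(target, otus, window = NULL,
                           config = primer_config(),
                           target_id = "target") {
  if (is.data.frame(target)) target <- target$sequence
  stopifnot(length(target) >= 1L)
  if (length(unique(nchar(target))) != 1L) {
    abort(
      "grouped target members must have equal length (aligned templates)",
      class = "darktaxa_validation_error"
    )
  }
  tlen <- nchar(target[1])
  if (is.null(window)) window <- c(0L, tlen)
  w_start <- window[1]
  w_end <- window[2]
  if (w_end - w_start < config$len_min) {
    abort("variable window shorter than the minimum primer length",
      class = "darktaxa_validation_error"
    )
  }
  lens <- config$len_min:config$len_max
  enum <- tidyr::crossing(len = lens, start = seq(w_start, w_end - min(lens))) |>
    filter(.data$start + .data$len <= w_end) |>
    mutate(
      slice = substring(target[1], .data$start + 1L, .data$start + .data$len)
    )
  # identical across all group members, and unambiguous
  keep <- !grepl("[^ACGT]", enum$slice)
  for (memb in target[-1]) {
    keep <- keep &
      substring(memb, enum$start + 1L, enum$start + enum$len) == enum$slice
  }
  enum <- enum[keep, , drop = FALSE]
  if (nrow(enum) == 0L) {
    return(empty_candidates(target_id))
  }
  cand <- bind_rows(
    tibble(
      sequence = enum$slice, direction = "forward",
      template_start = enum$start, template_end = enum$start + enum$len
    ),
    tibble(
      sequence = reverse_complement(enum$slice), direction = "reverse",
      template_start = enum$start, template_end = enum$start + enum$len
    )
  )
  scored <- evaluate_criteria(cand, otus, window, config) |>
    filter(.data$pass) |>
    mutate(target_id = target_id) |>
    group_by(.data$direction) |>
    arrange(
      .data$three_prime_hits, abs(.data$Tm - 56), -.data$length,
      .data$template_start,
      .by_group = TRUE
    ) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select(
      "target_id", "direction", "sequence", "template_start",
      "template_end", "length", "Tm", "GC_pct", "three_prime_hits",
      "distance_to_flank", "rank"
    )
  scored
}

empty_candidates <- function(target_id) {
  tibble(
    target_id = character(0), direction = character(0),
    sequence = character(0), template_start = integer(0),
    template_end = integer(0), length = integer(0), Tm = numeric(0),
    GC_pct = numeric(0), three_prime_hits = integer(0),
    distance_to_flank = integer(0), rank = integer(0)
  )
}

#' Pair specific primers with universal rRNA primers
#'
#' Reverse specific primers (pointing back into the 18S gene) are paired
#' with the forward universal primers NS5a and NS7a to amplify the 18S
#' gene; forward specific primers are paired with the reverse universal
#' primers TW13 and LR5 to amplify the 28S gene. Requesting a pairing
#' that violates this orientation contract is an error.
#'
#' @param candidates Tibble of criteria-passing candidates (from
#'   [design_primers()]).
#' @param universal Universal primer table
#'   ([default_universal_primers()]).
#' @param universal_names Optional restriction to specific universal
#'   primer names; names incompatible with a candidate's direction are
#'   refused.
#' @return One row per (candidate, universal partner): the candidate
#'   columns plus `primer_seq`, `universal_partner`, `universal_seq`,
#'   `amplified_gene`.
#' @export
pair_with_universal <- function(candidates,
                                universal = default_universal_primers(),
                                universal_names = NULL) {
  amp <- universal[universal$role == "amplification", ]
  need <- c("NS5a", "NS7a", "TW13", "LR5")
  if (is.null(universal_names)) {
    missing_u <- setdiff(need, amp$name)
    if (length(missing_u)) {
      abort(
        paste0(
          "universal primer sequence(s) missing from config: ",
          paste(missing_u, collapse = ", ")
        ),
        class = "darktaxa_validation_error"
      )
    }
  }
  pair_one <- function(direction) {
    partners <- if (direction == "reverse") {
      amp[amp$direction == "forward" & amp$gene == "SSU18S", ]
    } else {
      amp[amp$direction == "reverse" & amp$gene == "LSU28S", ]
    }
    if (!is.null(universal_names)) {
      bad <- setdiff(
        intersect(universal_names, amp$name),
        partners$name
      )
      if (length(bad) && any(candidates$direction == direction)) {
        abort(
          paste0(
            "orientation contract: ", direction,
            " specific primers cannot pair with ",
            paste(bad, collapse = ", ")
          ),
          class = "darktaxa_validation_error"
        )
      }
      partners <- partners[partners$name %in% universal_names, ]
    }
    partners
  }
  out <- list()
  for (dir in unique(candidates$direction)) {
    partners <- pair_one(dir)
    sub <- candidates[candidates$direction == dir, ]
    for (i in seq_len(nrow(partners))) {
      out[[length(out) + 1L]] <- sub |>
        mutate(
          primer_seq = .data$sequence,
          universal_partner = partners$name[i],
          universal_seq = partners$sequence[i],
          amplified_gene = partners$gene[i]
        )
    }
  }
  if (!length(out)) {
    return(tibble())
  }
  bind_rows(out) |>
    arrange(.data$target_id, .data$direction, .data$rank, .data$universal_partner)
}

# Plus-strand binding sites of a primer on a set of templates.
# role "forward": the primer sequence itself must occur; its 3' decamer
# (site suffix) must match exactly. role "reverse": the site is the
# reverse complement of the primer; the primer's 3' decamer maps to the
# *first* 10 bases of the site.
binding_sites <- function(primer, templates, role, max_mismatch = 0) {
  site <- if (role == "forward") primer else reverse_complement(primer)
  hits <- Biostrings::vmatchPattern(
    site, Biostrings::DNAStringSet(templates),
    max.mismatch = max_mismatch
  )
  lapply(seq_along(templates), function(j) {
    st <- Biostrings::startIndex(hits)[[j]]
    if (is.null(st) || length(st) == 0L) {
      return(integer(0))
    }
    if (max_mismatch > 0L) {
      # mismatches are never tolerated in the 3' decamer
      dec_ok <- vapply(st, function(s) {
        if (role == "forward") {
          substr(templates[j], s + nchar(site) - 10L, s + nchar(site) - 1L) ==
            substr(site, nchar(site) - 9L, nchar(site))
        } else {
          substr(templates[j], s, s + 9L) == substr(site, 1L, 10L)
        }
      }, logical(1))
      st <- st[dec_ok]
    }
    st
  })
}

#' In-silico PCR of primer pairs against an operon database
#'
#' For each pair and template, reports every product where the forward
#' and reverse primers bind convergently within `max_product` bases.
#' Binding is an exact plus-strand match of the primer (forward role) or
#' of its reverse complement (reverse role), or up to `max_mismatch`
#' substitutions that never fall in the 3' decamer. More than one product
#' on a template marks the pair as unspecific there.
#'
#' @param pairs Output of [pair_with_universal()], or a primer table read
#'   back with [read_primer_table()] (the universal oligo sequence is then
#'   looked up in `universal`).
#' @param operons Tibble with `template_id` and `sequence` (full
#'   templates; a `clade_id` column, if present, is carried through).
#' @param max_mismatch Substitutions tolerated outside the 3' decamer.
#'   Default 0 (exact).
#' @param max_product Maximum product length in bases.
#' @param universal Universal primer table used to resolve
#'   `universal_partner` names when `pairs` carries no `universal_seq`
#'   column.
#' @return A tibble with one row per predicted amplicon: `target_id`,
#'   `direction`, `primer_seq`, `universal_partner`, `template_id`,
#'   `start`, `end` (0-based half-open), `product_length`, `n_products`
#'   (products of this pair on this template) and `unspecific`.
#' @export
insilico_pcr <- function(pairs, operons, max_mismatch = 0,
                         max_product = 3000L,
                         universal = default_universal_primers()) {
  if (!"universal_seq" %in% names(pairs)) {
    idx <- match(pairs$universal_partner, universal$name)
    if (anyNA(idx)) {
      abort("universal primer sequence missing from config",
        class = "darktaxa_validation_error"
      )
    }
    pairs$universal_seq <- universal$sequence[idx]
  }
  templates <- operons$sequence
  out <- list()
  key_cols <- c("target_id", "direction", "primer_seq", "universal_partner")
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    if (p$direction == "forward") {
      fwd <- p$primer_seq
      rev <- p$universal_seq
    } else {
      fwd <- p$universal_seq
      rev <- p$primer_seq
    }
    f_sites <- binding_sites(fwd, templates, "forward", max_mismatch)
    r_sites <- binding_sites(rev, templates, "reverse", max_mismatch)
    for (j in seq_along(templates)) {
      fs <- f_sites[[j]]
      rs <- r_sites[[j]]
      if (!length(fs) || !length(rs)) next
      combos <- expand.grid(f = fs, r = rs)
      combos$end <- combos$r + nchar(reverse_complement(rev)) - 1L
      combos$len <- combos$end - combos$f + 1L
      combos <- combos[combos$len > 0 & combos$len <= max_product, ,
        drop = FALSE
      ]
      if (!nrow(combos)) next
      out[[length(out) + 1L]] <- tibble(
        target_id = p$target_id,
        direction = p$direction,
        primer_seq = p$primer_seq,
        universal_partner = p$universal_partner,
        template_id = operons$template_id[j],
        clade_id = if ("clade_id" %in% names(operons)) {
          operons$clade_id[j]
        } else {
          NA_character_
        },
        start = combos$f - 1L, # back to 0-based half-open
        end = combos$end,
        product_length = combos$len
      )
    }
  }
  if (!length(out)) {
    return(tibble(
      target_id = character(0), direction = character(0),
      primer_seq = character(0), universal_partner = character(0),
      template_id = character(0), clade_id = character(0),
      start = integer(0), end = integer(0), product_length = integer(0),
      n_products = integer(0), unspecific = logical(0)
    ))
  }
  bind_rows(out) |>
    group_by(dplyr::across(dplyr::all_of(c(key_cols, "template_id")))) |>
    mutate(n_products = n(), unspecific = n() > 1L) |>
    ungroup()
}
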