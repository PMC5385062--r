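region_rank <- c(SSU18S = 1L, ITS = 2L, LSU28S = 3L)

# Best ungapped dovetail (suffix-prefix, containment allowed) placement of
# `b` against `a`, over both orientations of `b`. The entire overlapping
# window is compared at each offset (no trimming inside the overlap) —
# this is what lets a chimeric junction depress the overlap identity
# instead of being clipped away. Score = matches - mismatches; ties prefer
# the longer overlap.
best_dovetail <- function(a, b) {
  ra <- utf8ToInt(a)
  na <- length(ra)
  best <- list(score = -Inf, overlap = 0L, identity = NA_real_,
               offset = NA_integer_, orientation = NA_character_)
  for (orient in c("forward", "revcomp")) {
    bb <- if (orient == "forward") b else reverse_complement(b)
    rb <- utf8ToInt(bb)
    nb <- length(rb)
    for (d in seq.int(-(nb - 1L), na - 1L)) {
      a_lo <- max(1L, d + 1L)
      a_hi <- min(na, d + nb)
      len <- a_hi - a_lo + 1L
      if (len <= 0L) next
      m <- sum(ra[a_lo:a_hi] == rb[(a_lo - d):(a_hi - d)])
      score <- 2L * m - len
      if (score > best$score ||
        (score == best$score && len > best$overlap)) {
        best <- list(
          score = score, overlap = len, identity = m / len,
          offset = d, orientation = orient
        )
      }
    }
  }
  best
}

#' Overlap consistency between two read segments
#'
#' Computes the best ungapped dovetail alignment of `seg_b` against
#' `seg_a` (both orientations of `seg_b`; the full overlap window is
#' scored at every offset) and classifies the pair: `ok` when the overlap
#' spans at least `min_overlap` bases at identity at least
#' `min_identity`; `chimera_flag` when a long overlap disagrees (identity
#' below the threshold) — the signature of a chimeric junction inside the
#' overlap; `no_overlap` otherwise.
#'
#' @param seg_a,seg_b DNA strings (non-empty).
#' @param min_overlap Minimum overlap in bases for a verdict. Default 30.
#' @param min_identity Identity threshold inside the overlap. Default
#'   0.97.
#' @return A one-row tibble: `overlap`, `identity`, `status`,
#'   `orientation` (`"forward"`/`"revcomp"` of `seg_b`), `offset` (start
#'   of `seg_b` relative to `seg_a`, 0-based, may be negative), `score`.
#' @export
overlap_consistency <- function(seg_a, seg_b, min_overlap = 30,
                                min_identity = 0.97) {
  if (!nzchar(seg_a) || !nzchar(seg_b)) {
    abort("segments must be non-empty", class = "darktaxa_validation_error")
  }
  best <- best_dovetail(toupper(seg_a), toupper(seg_b))
  status <- if (best$overlap >= min_overlap && best$identity >= min_identity) {
    "ok"
  } else if (best$overlap >= min_overlap) {
    "chimera_flag"
  } else {
    "no_overlap"
  }
  tibble(
    overlap = best$overlap, identity = best$identity, status = status,
    orientation = best$orientation, offset = best$offset, score = best$score
  )
}

#' Assemble sequencing reads into a long rRNA construct
#'
#' Orders segments 18S -> ITS -> 28S by their claimed region, checks each
#' consecutive pair with [overlap_consistency()], and chains `ok`
#' overlaps into one merged sequence (merged length = sum of lengths -
#' sum of overlaps). Any `chimera_flag` or `no_overlap` verdict, or two
#' segments claiming the same region with conflicting sequence, aborts
#' merging with that status. Within an `ok` overlap, disagreeing bases
#' are resolved in favour of the Sanger-derived segment.
#'
#' @param segments Tibble with columns `read_id`, `sequence`,
#'   `claimed_region` (`"SSU18S"`, `"ITS"`, `"LSU28S"`) and `source`
#'   (`"sanger"` / `"pyrosequencing"`); 2-4 rows. Input order is
#'   irrelevant.
#' @param min_overlap,min_identity Passed to [overlap_consistency()].
#' @return An object of class `construct_report`: a list with `status`
#'   (`"ok"`, `"chimera_flag"`, `"no_overlap"`, `"conflict"`),
#'   `construct` (merged sequence or `NA`), `segments` (with construct
#'   offsets) and `junctions` (per-junction overlap table).
#' @export
assemble_construct <- function(segments, min_overlap = 30,
                               min_identity = 0.97) {
  stopifnot(all(
    c("read_id", "sequence", "claimed_region", "source") %in% names(segments)
  ))
  if (nrow(segments) < 2L || nrow(segments) > 4L) {
    abort("assemble_construct takes 2-4 segments",
      class = "darktaxa_validation_error"
    )
  }
  if (any(!nzchar(segments$sequence))) {
    abort("segments must be non-empty", class = "darktaxa_validation_error")
  }
  if (!all(segments$claimed_region %in% names(region_rank))) {
    abort("claimed_region must be one of SSU18S, ITS, LSU28S",
      class = "darktaxa_validation_error"
    )
  }
  segments <- segments |>
    arrange(
      region_rank[.data$claimed_region],
      match(.data$source, c("sanger", "pyrosequencing")),
      .data$read_id
    )
  # duplicate region claims: identical sequence -> dedupe, else conflict
  dup <- duplicated(segments$claimed_region)
  if (any(dup)) {
    for (reg in unique(segments$claimed_region[dup])) {
      seqs <- unique(segments$sequence[segments$claimed_region == reg])
      if (length(seqs) > 1L) {
        return(new_construct_report("conflict", segments))
      }
    }
    segments <- segments[!dup, , drop = FALSE]
    if (nrow(segments) < 2L) {
      return(new_construct_report("ok", segments,
        construct = segments$sequence[1],
        offsets = 0L, junctions = empty_junctions()
      ))
    }
  }
  construct <- segments$sequence[1]
  src <- segments$source[1]
  offsets <- integer(nrow(segments))
  junctions <- list()
  for (i in 2L:nrow(segments)) {
    oc <- overlap_consistency(
      construct, segments$sequence[i], min_overlap, min_identity
    )
    junctions[[i - 1L]] <- oc |>
      mutate(
        from = segments$read_id[i - 1L], to = segments$read_id[i],
        .before = 1L
      )
    if (oc$status != "ok") {
      return(new_construct_report(
        oc$status, segments,
        junctions = bind_rows(junctions)
      ))
    }
    b <- if (oc$orientation == "revcomp") {
      reverse_complement(segments$sequence[i])
    } else {
      segments$sequence[i]
    }
    d <- oc$offset
    na_len <- nchar(construct)
    nb <- nchar(b)
    if (d < 0L) {
      # next segment extends left of the running construct; should not
      # happen with region-ordered input but handled for robustness
      merged <- merge_overlap(
        b, construct, -d, segments$source[i], src, min_identity
      )
      offsets[seq_len(i - 1L)] <- offsets[seq_len(i - 1L)] - d
      offsets[i] <- 0L
      construct <- merged
    } else if (d + nb <= na_len) {
      offsets[i] <- d # containment: nothing to append
    } else {
      construct <- merge_overlap(
        construct, b, d, src, segments$source[i], min_identity
      )
      offsets[i] <- d
    }
    if (segments$source[i] == "sanger") src <- "sanger"
  }
  new_construct_report("ok", segments,
    construct = construct, offsets = offsets,
    junctions = bind_rows(junctions)
  )
}

# Merge b (starting at 0-based offset d inside/after a) onto a; bases in
# the overlap come from the sanger-derived side when the two disagree.
merge_overlap <- function(a, b, d, source_a, source_b, min_identity) {
  na_len <- nchar(a)
  if (source_b == "sanger" && source_a != "sanger") {
    paste0(substr(a, 1L, d), b)
  } else {
    paste0(a, substr(b, na_len - d + 1L, nchar(b)))
  }
}

empty_junctions <- function() {
  tibble(
    from = character(0), to = character(0), overlap = integer(0),
    identity = numeric(0), status = character(0), orientation = character(0),
    offset = integer(0), score = integer(0)
  )
}

new_construct_report <- function(status, segments, construct = NA_character_,
                                 offsets = NULL, junctions = NULL) {
  segs <- segments |> select("read_id", "claimed_region", "source")
  if (!is.null(offsets)) segs$offset <- offsets
  structure(
    list(
      status = status,
      construct = construct,
      segments = segs,
      junctions = junctions %||% empty_junctions()
    ),
    class = "construct_report"
  )
}

#' @export
print.construct_report <- function(x, ...) {
  cat("<construct_report> status:", x$status)
  if (!is.na(x$construct)) cat(", length:", nchar(x$construct))
  cat("\n")
  print(x$segments)
  invisible(x)
}
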