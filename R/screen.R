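#' Screen OTUs that are unidentifiable against named references
#'
#' Returns the OTUs whose maximum pairwise identity (see
#' [pairwise_identity()]) against every named reference is below
#' `threshold` — the operational definition of a "dark" OTU: no match at
#' or above the threshold to any species with a Latin binomial. The best
#' reference hit is retained for every OTU.
#'
#' @param otus Tibble with columns `otu_id` and `sequence`.
#' @param references Tibble with columns `ref_id`, `binomial`, `sequence`;
#'   must be non-empty (an empty reference set cannot certify
#'   unidentifiability and is an error).
#' @param threshold Identity threshold; OTUs strictly below it are
#'   retained. Default 0.80.
#' @param keep_all If `TRUE`, return the screening report for all OTUs
#'   with a logical `unidentifiable` column instead of the retained
#'   subset.
#' @return A tibble of retained OTUs (or all OTUs when `keep_all`), with
#'   `best_ref_id`, `best_identity` and `best_overlap` columns appended.
#' @export
screen_unidentifiable <- function(otus, references, threshold = 0.80,
                                  keep_all = FALSE) {
  stopifnot(all(c("otu_id", "sequence") %in% names(otus)))
  if (is.null(references) || nrow(references) == 0L) {
    abort(
      "empty reference set: cannot certify unidentifiability",
      class = "darktaxa_validation_error"
    )
  }
  if (!all(nzchar(references$binomial))) {
    abort("references must carry a non-empty binomial",
      class = "darktaxa_validation_error"
    )
  }
  best_id <- rep(-Inf, nrow(otus))
  best_ref <- rep(NA_character_, nrow(otus))
  best_ov <- rep(NA_integer_, nrow(otus))
  for (j in seq_len(nrow(references))) {
    al <- align_overlap(otus$sequence, references$sequence[j])
    idj <- Biostrings::nmatch(al) / Biostrings::nchar(al)
    better <- idj > best_id
    best_id[better] <- idj[better]
    best_ref[better] <- references$ref_id[j]
    best_ov[better] <- Biostrings::nchar(al)[better]
  }
  report <- otus |>
    mutate(
      best_ref_id = best_ref,
      best_identity = best_id,
      best_overlap = best_ov,
      unidentifiable = best_id < threshold
    )
  if (keep_all) {
    return(report)
  }
  report |>
    filter(.data$unidentifiable) |>
    select(-"unidentifiable")
}

#' Single-linkage clustering of OTUs by pairwise identity
#'
#' Two OTUs are linked iff their pairwise identity is at least `threshold`
#' and the aligned overlap spans at least `min_overlap` columns; clusters
#' are the connected components of the resulting link graph. The output is
#' canonical (independent of input order): clusters are numbered by their
#' lexicographically smallest member id.
#'
#' @param otus Tibble with columns `otu_id` and `sequence`.
#' @param threshold Linking identity threshold. Default 0.80.
#' @param min_overlap Minimum aligned coverage in bases. Default 100.
#' @return A tibble with columns `otu_id`, `cluster_id`, `cluster_size`,
#'   sorted by cluster then member id.
#' @export
single_linkage_cluster <- function(otus, threshold = 0.80, min_overlap = 100) {
  stopifnot(nrow(otus) >= 1L)
  ord <- order(otus$otu_id)
  seqs <- otus$sequence[ord]
  ids <- otus$otu_id[ord]
  mats <- identity_matrix(seqs, ids)
  adj <- (mats$identity >= threshold) & (mats$overlap >= min_overlap)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # canonical numbering: order components by smallest member id
  first_member <- tapply(ids, comp, min)
  relabel <- rank(first_member)
  cluster_idx <- relabel[as.character(comp)]
  out <- tibble(
    otu_id = ids,
    cluster_id = sprintf("C%03d", cluster_idx)
  ) |>
    group_by(.data$cluster_id) |>
    mutate(cluster_size = n()) |>
    ungroup() |>
    arrange(.data$cluster_id, .data$otu_id)
  out
}

#' Select primer-design targets from OTU clusters
#'
#' Within each cluster, OTUs are regrouped at a stricter identity
#' (`group_identity`, exclusive): each connected component with two or
#' more members becomes a *grouped* target (one primer set serving nearly
#' identical OTUs), and each singleton component becomes an *individual*
#' target. Every cluster therefore contributes at least one target, so in
#' particular all major clusters (size > `major_cluster_size`) are
#' covered. When `max_individual_per_cluster` is finite, only the
#' most-abundant individual candidates per cluster are kept (total reads
#' descending, ties broken by lexicographic id) — the most abundant member
#' being the most recoverable by PCR.
#'
#' @param clusters Output of [single_linkage_cluster()].
#' @param otus Tibble with `otu_id`, `sequence` and optionally
#'   `total_reads` (used for the abundance tie-break; missing = 0).
#' @param group_identity Exclusive identity bound for grouping. Default
#'   0.95.
#' @param major_cluster_size Clusters larger than this are "major".
#'   Default 10.
#' @param max_individual_per_cluster Cap on individual targets per
#'   cluster. Default `Inf` (every component is targeted).
#' @return A tibble with columns `target_id`, `cluster_id`, `type`
#'   (`"individual"` or `"group"`), `members` (list column of otu ids),
#'   `n_members`, and `major` (whether the source cluster is major).
#' @export
select_targets <- function(clusters, otus, group_identity = 0.95,
                           major_cluster_size = 10,
                           max_individual_per_cluster = Inf) {
  stopifnot(all(c("otu_id", "cluster_id") %in% names(clusters)))
  reads <- otus$total_reads %||% rep(0, nrow(otus))
  abundance <- setNames(as.numeric(reads), otus$otu_id)
  seqs <- setNames(otus$sequence, otus$otu_id)

  rows <- list()
  for (cl in sort(unique(clusters$cluster_id))) {
    members <- sort(clusters$otu_id[clusters$cluster_id == cl])
    major <- length(members) > major_cluster_size
    if (length(members) == 1L) {
      comp_sets <- list(members)
    } else {
      mats <- identity_matrix(unname(seqs[members]), members)
      adj <- mats$identity > group_identity
      diag(adj) <- FALSE
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      memb <- igraph::components(g)$membership
      comp_sets <- split(members, memb)
    }
    grouped <- comp_sets[lengths(comp_sets) >= 2L]
    singles <- unlist(comp_sets[lengths(comp_sets) == 1L], use.names = FALSE)
    if (is.finite(max_individual_per_cluster) && length(singles)) {
      ord <- order(-abundance[singles], singles)
      singles <- singles[head(ord, max_individual_per_cluster)]
    }
    for (gset in grouped) {
      rows[[length(rows) + 1L]] <- tibble(
        cluster_id = cl, type = "group",
        members = list(sort(gset)), n_members = length(gset), major = major
      )
    }
    for (s in sort(singles)) {
      rows[[length(rows) + 1L]] <- tibble(
        cluster_id = cl, type = "individual",
        members = list(s), n_members = 1L, major = major
      )
    }
  }
  out <- bind_rows(rows)
  # stable, readable target ids; no otu may appear in two targets
  out <- out |>
    arrange(.data$cluster_id, .data$type, map_chr(.data$members, 1)) |>
    mutate(
      target_id = sprintf(
        "%s_%s%02d", .data$cluster_id,
        ifelse(.data$type == "group", "G", "T"),
        stats::ave(seq_len(nrow(out)), .data$cluster_id, .data$type,
          FUN = seq_along
        )
      )
    ) |>
    select(
      "target_id", "cluster_id", "type", "members", "n_members", "major"
    )
  stopifnot(!anyDuplicated(unlist(out$members)))
  out
}
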