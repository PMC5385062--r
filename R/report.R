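#' Targeting arithmetic summary
#'
#' Bookkeeping for a primer-design campaign: individual targets plus the
#' member OTUs of grouped targets give the total number of targeted OTUs.
#'
#' @param n_individual Number of individually targeted OTUs.
#' @param n_groups Number of grouped targets.
#' @param n_group_otus Total OTUs contained in the grouped targets.
#' @return A one-row tibble with `n_individual`, `n_groups`,
#'   `n_group_otus`, `n_targets` (individual + groups) and
#'   `n_targeted_otus` (individual + group members).
#' @export
targeting_summary <- function(n_individual, n_groups, n_group_otus) {
  stopifnot(n_group_otus >= 2 * n_groups || n_groups == 0)
  tibble(
    n_individual = n_individual,
    n_groups = n_groups,
    n_group_otus = n_group_otus,
    n_targets = n_individual + n_groups,
    n_targeted_otus = n_individual + n_group_otus
  )
}

#' @rdname targeting_summary
#' @param targets A target set tibble from [select_targets()]; counts are
#'   derived from it.
#' @export
summarize_target_set <- function(targets) {
  grouped <- targets[targets$type == "group", ]
  targeting_summary(
    n_individual = sum(targets$type == "individual"),
    n_groups = nrow(grouped),
    n_group_otus = sum(grouped$n_members)
  )
}

#' Sequencing recovery summary
#'
#' @param n_targeted Number of targeted OTUs.
#' @param n_failed Number of OTUs for which sequencing failed completely.
#' @return A one-row tibble with `n_targeted`, `n_failed`, `n_recovered`
#'   and `recovery_pct` (percent of targeted OTUs recovered).
#' @export
recovery_summary <- function(n_targeted, n_failed) {
  stopifnot(n_failed >= 0, n_failed <= n_targeted, n_targeted > 0)
  tibble(
    n_targeted = n_targeted,
    n_failed = n_failed,
    n_recovered = n_targeted - n_failed,
    recovery_pct = 100 * (n_targeted - n_failed) / n_targeted
  )
}

#' Novel-lineage composition summary
#'
#' Arithmetic over the recovered novel groups: clades plus single-sequence
#' branches give the group total; the share of a focal phylum and the
#' share of multi-OTU groups are reported as percentages.
#'
#' @param n_clades,n_branches Counts of clades and branches overall.
#' @param n_phylum_clades,n_phylum_branches Counts within the focal
#'   phylum.
#' @param n_multi_otu Number of groups comprising more than one OTU.
#' @return A one-row tibble with `n_groups`, `phylum_share_pct`,
#'   `multi_otu_share_pct`.
#' @export
lineage_summary <- function(n_clades, n_branches,
                            n_phylum_clades = 0, n_phylum_branches = 0,
                            n_multi_otu = 0) {
  n_groups <- n_clades + n_branches
  stopifnot(
    n_groups > 0,
    n_phylum_clades <= n_clades, n_phylum_branches <= n_branches,
    n_multi_otu <= n_groups
  )
  tibble(
    n_groups = n_groups,
    phylum_share_pct = 100 * (n_phylum_clades + n_phylum_branches) / n_groups,
    multi_otu_share_pct = 100 * n_multi_otu / n_groups
  )
}
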