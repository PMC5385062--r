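#' Pipeline configuration
#'
#' Collects every stage's thresholds with the workflow's canonical
#' defaults: 0.80 identity / 100-base coverage single linkage, >0.95
#' within-group identity, >10-OTU major clusters, primer criteria 54-58
#' degC / 33-62% GC / 16-21 bases / <20 decamer hits / >20-base flanks,
#' 30-base 0.97-identity overlap QC, SD ratio > 2 with Levene alpha 0.05,
#' 999 permutations, and 10-fold cross-validation repeated 100 times.
#'
#' @param seed Master seed for all stochastic stages.
#' @param sim A [sim_config()] (its seed is overridden by `seed`).
#' @param screen_threshold Reference-identity screen bound. Default 0.80.
#' @param cluster_threshold,min_overlap Single-linkage parameters.
#' @param group_identity,major_cluster_size Target-selection parameters.
#' @param primer A [primer_config()].
#' @param qc_min_overlap,qc_min_identity Construct QC parameters.
#' @param alpha,sd_ratio_min Niche-narrowness parameters.
#' @param n_perm Permutations for the categorical bias test.
#' @param cv_k,cv_repeats Cross-validation harness parameters.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            screen_threshold = 0.80,
                            cluster_threshold = 0.80,
                            min_overlap = 100L,
                            group_identity = 0.95,
                            major_cluster_size = 10L,
                            primer = primer_config(),
                            qc_min_overlap = 30L,
                            qc_min_identity = 0.97,
                            alpha = 0.05,
                            sd_ratio_min = 2,
                            n_perm = 999L,
                            cv_k = 10L,
                            cv_repeats = 100L) {
  sim$seed <- as.integer(seed)
  structure(
    list(
      seed = as.integer(seed), sim = sim,
      screen_threshold = screen_threshold,
      cluster_threshold = cluster_threshold,
      min_overlap = as.integer(min_overlap),
      group_identity = group_identity,
      major_cluster_size = as.integer(major_cluster_size),
      primer = primer,
      qc_min_overlap = as.integer(qc_min_overlap),
      qc_min_identity = qc_min_identity,
      alpha = alpha, sd_ratio_min = sd_ratio_min,
      n_perm = as.integer(n_perm),
      cv_k = as.integer(cv_k), cv_repeats = as.integer(cv_repeats)
    ),
    class = "pipeline_config"
  )
}

pipeline_stages <- c(
  "simulate", "screen", "cluster", "design", "qc", "niche", "all"
)

stage_file <- function(out_dir, name) file.path(out_dir, name)

require_stage_input <- function(path, stage) {
  if (!file.exists(path)) {
    abort(
      paste0("stage '", stage, "' requires missing input file: ", path),
      class = "darktaxa_io_error"
    )
  }
  path
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' Stage-per-subcommand driver: each stage reads its inputs from
#' `out_dir`, writes its artifacts there, and appends a machine-readable
#' provenance record (`provenance.json`: stage, seed, config hash,
#' package version, timestamp) sufficient to reproduce the run. `"all"`
#' chains `simulate`, `screen`, `cluster`, `design`, `qc` and `niche`,
#' feeding each output forward.
#'
#' @param stage One of `"simulate"`, `"screen"`, `"cluster"`, `"design"`,
#'   `"qc"`, `"niche"`, `"all"`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return A named list of the stage's in-memory results, invisibly.
#' @export
run_stage <- function(stage, config = pipeline_config(), out_dir) {
  if (length(stage) != 1L || !stage %in% pipeline_stages) {
    abort(
      paste0(
        "unknown stage '", paste(stage, collapse = ","),
        "'; usage: run_stage(<",
        paste(pipeline_stages, collapse = "|"), ">, config, out_dir)"
      ),
      class = "darktaxa_usage_error"
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    res <- list()
    for (s in setdiff(pipeline_stages, "all")) {
      res[[s]] <- run_stage(s, config, out_dir)
    }
    return(invisible(res))
  }
  result <- switch(stage,
    simulate = stage_simulate(config, out_dir),
    screen = stage_screen(config, out_dir),
    cluster = stage_cluster(config, out_dir),
    design = stage_design(config, out_dir),
    qc = stage_qc(config, out_dir),
    niche = stage_niche(config, out_dir)
  )
  record_provenance(stage, config, out_dir)
  invisible(result)
}

record_provenance <- function(stage, config, out_dir) {
  path <- stage_file(out_dir, "provenance.json")
  prev <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    list()
  }
  prev[[length(prev) + 1L]] <- list(
    stage = stage,
    seed = config$seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("darktaxa")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(prev, path, auto_unbox = TRUE, pretty = TRUE)
}

stage_simulate <- function(config, out_dir) {
  fam <- generate_operon_family(config$sim)
  occ <- generate_occurrences(
    config$sim, fam$otus[, c("otu_id", "clade_id")]
  )
  refs <- generate_references(
    n = 10,
    length = as.integer(config$sim$region_lengths[["ITS2"]]),
    seed = config$seed + 2L
  )
  write_fasta(
    fam$otus |> rename(id = "otu_id"),
    stage_file(out_dir, "otus.fasta")
  )
  write_fasta(
    fam$operons |> rename(id = "template_id"),
    stage_file(out_dir, "operons.fasta")
  )
  write_fasta(
    refs |>
      mutate(desc = paste(.data$ref_id, .data$binomial)) |>
      rename(id = "ref_id"),
    stage_file(out_dir, "references.fasta")
  )
  readr::write_tsv(
    fam$otus[, c("otu_id", "clade_id", "total_reads")],
    stage_file(out_dir, "truth.tsv")
  )
  write_site_table(occ$sites, stage_file(out_dir, "sites.tsv"))
  write_occurrence_table(
    occ$occurrence, stage_file(out_dir, "occurrence.tsv")
  )
  list(family = fam, occurrence = occ, references = refs)
}

read_simulated <- function(out_dir, stage) {
  otus <- read_fasta(
    require_stage_input(stage_file(out_dir, "otus.fasta"), stage)
  ) |> rename(otu_id = "id")
  truth <- readr::read_tsv(
    require_stage_input(stage_file(out_dir, "truth.tsv"), stage),
    col_types = "cci", progress = FALSE
  )
  left_join(otus, truth, by = "otu_id")
}

stage_screen <- function(config, out_dir) {
  otus <- read_simulated(out_dir, "screen")
  ref_fa <- read_fasta(
    require_stage_input(stage_file(out_dir, "references.fasta"), "screen")
  )
  refs <- tibble(
    ref_id = ref_fa$id,
    binomial = sub("^\\S+\\s*", "", ref_fa$desc),
    sequence = ref_fa$sequence
  )
  refs$binomial[!nzchar(refs$binomial)] <- refs$ref_id[!nzchar(refs$binomial)]
  screened <- screen_unidentifiable(
    otus, refs,
    threshold = config$screen_threshold, keep_all = TRUE
  )
  readr::write_tsv(
    screened |> select(-"sequence"),
    stage_file(out_dir, "screen.tsv")
  )
  screened
}

stage_cluster <- function(config, out_dir) {
  screened <- readr::read_tsv(
    require_stage_input(stage_file(out_dir, "screen.tsv"), "cluster"),
    col_types = readr::cols(), progress = FALSE
  )
  otus <- read_simulated(out_dir, "cluster") |>
    filter(.data$otu_id %in% screened$otu_id[screened$unidentifiable])
  clusters <- single_linkage_cluster(
    otus,
    threshold = config$cluster_threshold,
    min_overlap = config$min_overlap
  )
  targets <- select_targets(
    clusters, otus,
    group_identity = config$group_identity,
    major_cluster_size = config$major_cluster_size
  )
  membership <- clusters |>
    left_join(
      targets |>
        tidyr::unnest(cols = "members") |>
        select(otu_id = "members", "target_id"),
      by = "otu_id"
    ) |>
    mutate(target_flag = !is.na(.data$target_id))
  readr::write_tsv(membership, stage_file(out_dir, "clusters.tsv"))
  readr::write_tsv(
    targets |>
      tidyr::unnest(cols = "members") |>
      rename(otu_id = "members"),
    stage_file(out_dir, "targets.tsv")
  )
  list(clusters = clusters, targets = targets)
}

stage_design <- function(config, out_dir) {
  targets_long <- readr::read_tsv(
    require_stage_input(stage_file(out_dir, "targets.tsv"), "design"),
    col_types = readr::cols(), progress = FALSE
  )
  otus <- read_simulated(out_dir, "design")
  seqs <- setNames(otus$sequence, otus$otu_id)
  reads <- setNames(
    otus$total_reads %||% rep(0, nrow(otus)), otus$otu_id
  )
  pairs_all <- list()
  for (tid in unique(targets_long$target_id)) {
    members <- targets_long$otu_id[targets_long$target_id == tid]
    cand <- design_primers(
      unname(seqs[members]), otus,
      config = config$primer, target_id = tid
    )
    if (nrow(cand) == 0L && length(members) > 1L) {
      # no oligo serves the whole group: fall back to an individual
      # primer for the most abundant member, as a bench workflow would
      best <- members[order(-reads[members], members)][1L]
      cand <- design_primers(
        seqs[[best]], otus,
        config = config$primer,
        target_id = paste0(tid, ".", best)
      )
    }
    if (nrow(cand)) {
      pairs_all[[tid]] <- pair_with_universal(
        cand, config$sim$universal_primers
      )
    }
  }
  pairs <- if (length(pairs_all)) bind_rows(pairs_all) else tibble()
  write_primer_table(pairs, stage_file(out_dir, "primers.tsv"))
  pairs
}

stage_qc <- function(config, out_dir) {
  operon_fa <- read_fasta(
    require_stage_input(stage_file(out_dir, "operons.fasta"), "qc")
  )
  regions <- region_map(config$sim$region_lengths)
  reports <- purrr::map(seq_len(nrow(operon_fa)), function(i) {
    reads <- operon_read_set(operon_fa$sequence[i], regions)
    rep <- assemble_construct(
      reads,
      min_overlap = config$qc_min_overlap,
      min_identity = config$qc_min_identity
    )
    tibble(
      template_id = operon_fa$id[i],
      status = rep$status,
      construct_length = ifelse(is.na(rep$construct), NA_integer_,
        nchar(rep$construct)
      )
    )
  }) |> list_rbind()
  readr::write_tsv(reports, stage_file(out_dir, "construct_qc.tsv"))
  reports
}

stage_niche <- function(config, out_dir) {
  occ <- read_occurrence_table(
    require_stage_input(stage_file(out_dir, "occurrence.tsv"), "niche")
  )
  sites <- read_site_table(
    require_stage_input(stage_file(out_dir, "sites.tsv"), "niche")
  )
  truth <- readr::read_tsv(
    require_stage_input(stage_file(out_dir, "truth.tsv"), "niche"),
    col_types = "cci", progress = FALSE
  )
  groups <- truth |> select("otu_id", group_id = "clade_id")
  niche <- niche_narrowness(
    occ, sites, groups,
    alpha = config$alpha, sd_ratio_min = config$sd_ratio_min
  )
  bias <- with_seed(
    config$seed + 3L,
    categorical_bias_test(occ, sites, groups,
      factor = "biome", n_perm = config$n_perm
    )
  )
  write_niche_report(niche, stage_file(out_dir, "niche.tsv"), bias = bias)
  list(niche = niche, bias = bias)
}
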