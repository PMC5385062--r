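region_names <- c("SSU18S", "ITS1", "r5_8S", "ITS2", "LSU28S")
gene_regions <- c("SSU18S", "r5_8S", "LSU28S")

#' Universal rRNA primer configuration
#'
#' The broad-range eukaryote primers used to recover the conserved genes
#' flanking the ITS: NS5a/NS7a (forward, annealing in the 18S gene),
#' TW13/LR5 (reverse, annealing in the 28S gene) for amplification, and
#' ITS2/fITS7R/LR0R for sequencing. The oligo sequences shipped here are
#' clearly-labelled *synthetic stand-ins* (the real oligos are vendor
#' table data, not package truth); they are editable configuration, and
#' the operon simulator plants their binding sites so that in-silico PCR
#' can be exercised end to end. `site_offset` is the 0-based offset of the
#' planted binding site within `gene`.
#'
#' @return A tibble with columns `name`, `sequence`, `direction`, `gene`,
#'   `role`, `site_offset`.
#' @export
default_universal_primers <- function() {
  tibble(
    name = c("NS5a", "NS7a", "TW13", "LR5", "ITS2", "fITS7R", "LR0R"),
    sequence = c(
      "GCAAATTACCCAATCCTG", # synthetic stand-in oligos
      "GAGGCAATAACAGGTCTG",
      "GGTCCGTGTTTCAAGACG",
      "TCCTGAGGGAAACTTCGG",
      "GCTGCGTTCTTCATCGAT",
      "GTGARTCATCGAATCTTT",
      "ACCCGCTGAACTTAAGCA"
    ),
    direction = c(
      "forward", "forward", "reverse", "reverse",
      "reverse", "reverse", "forward"
    ),
    gene = c(
      "SSU18S", "SSU18S", "LSU28S", "LSU28S",
      "r5_8S", "r5_8S", "LSU28S"
    ),
    role = c(rep("amplification", 4L), rep("sequencing", 3L)),
    site_offset = c(60L, 300L, 250L, 480L, 100L, 30L, 5L)
  )
}

#' Simulation configuration for synthetic rRNA operon communities
#'
#' Defines the study conditions the synthetic-data generator emulates: a
#' root 18S-ITS1-5.8S-ITS2-28S operon, `n_clades` clade ancestors mutated
#' from it, `otus_per_clade` OTUs mutated from each ancestor (conserved
#' genes at `gene_mut_rate`, spacers at `its_mut_rate`, substitutions
#' only), and `n_sites` sampling sites whose per-clade occupancy follows a
#' Gaussian response to one environmental variable.
#'
#' Default rates are calibrated so that the expected pairwise ITS
#' divergence is 30% between clades and 3% within a clade (4% between
#' clades for the conserved genes), matching the similarity structure the
#' 80%/95% thresholds operate on.
#'
#' @param seed Integer seed; identical configs reproduce byte-identical
#'   output.
#' @param n_clades,otus_per_clade Community shape. Defaults 4 and 8.
#' @param its_mut_rate,gene_mut_rate Per-base substitution rates per unit
#'   branch depth for spacers and conserved genes.
#' @param clade_depth,otu_depth Branch depths of the clade-ancestor and
#'   OTU branches.
#' @param region_lengths Named integer vector of region lengths in bases.
#' @param n_sites Number of sampling sites. Default 200.
#' @param env_model Per-clade niche model: a tibble with columns
#'   `clade_id`, `variable`, `niche_mean`, `niche_sd` (`Inf` = flat
#'   niche), `max_occurrence_prob`. Defaults to [default_env_model()].
#' @param universal_primers Universal primer table whose binding sites the
#'   simulator plants (mutation-protected). Defaults to
#'   [default_universal_primers()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clades = 4L,
                       otus_per_clade = 8L,
                       its_mut_rate = divergence_to_rate(0.30),
                       gene_mut_rate = divergence_to_rate(0.04),
                       clade_depth = 1,
                       otu_depth = divergence_to_rate(0.03) /
                         divergence_to_rate(0.30),
                       region_lengths = c(
                         SSU18S = 500L, ITS1 = 150L, r5_8S = 155L,
                         ITS2 = 250L, LSU28S = 550L
                       ),
                       n_sites = 200L,
                       env_model = NULL,
                       universal_primers = default_universal_primers()) {
  stopifnot(
    its_mut_rate >= 0, gene_mut_rate >= 0,
    its_mut_rate <= 1, gene_mut_rate <= 1,
    its_mut_rate >= gene_mut_rate,
    n_clades >= 1, otus_per_clade >= 1, n_sites >= 1,
    identical(sort(names(region_lengths)), sort(region_names))
  )
  if (is.null(env_model)) {
    env_model <- default_env_model(n_clades)
  }
  stopifnot(all(env_model$niche_sd > 0))
  structure(
    list(
      seed = as.integer(seed),
      n_clades = as.integer(n_clades),
      otus_per_clade = as.integer(otus_per_clade),
      its_mut_rate = its_mut_rate,
      gene_mut_rate = gene_mut_rate,
      clade_depth = clade_depth,
      otu_depth = otu_depth,
      region_lengths = region_lengths[region_names],
      n_sites = as.integer(n_sites),
      env_model = env_model,
      universal_primers = universal_primers
    ),
    class = "sim_config"
  )
}

#' Default planted niche model
#'
#' The first clade receives a narrow soil-pH niche (SD one quarter of the
#' null SD of pH over its uniform sampling range), the second a narrow MAT
#' niche, and any further clades are niche-neutral (flat occupancy at a
#' lower rate) — giving every downstream statistic both positive and null
#' planted cases.
#'
#' @param n_clades Number of clades to cover.
#' @return A tibble usable as `env_model` in [sim_config()].
#' @export
default_env_model <- function(n_clades) {
  ids <- sprintf("clade_%02d", seq_len(n_clades))
  out <- tibble(
    clade_id = ids,
    variable = "pH",
    niche_mean = 5.75,
    niche_sd = Inf,
    max_occurrence_prob = 0.3
  )
  if (n_clades >= 1) {
    out$niche_sd[1] <- 0.25 * (8.5 - 3) / sqrt(12)
    out$max_occurrence_prob[1] <- 0.8
  }
  if (n_clades >= 2) {
    out$variable[2] <- "MAT"
    out$niche_mean[2] <- 11.5
    out$niche_sd[2] <- 0.25 * (28 - -5) / sqrt(12)
    out$max_occurrence_prob[2] <- 0.8
  }
  out
}

# 0-based half-open region map from a lengths vector.
region_map <- function(region_lengths) {
  ends <- cumsum(as.integer(region_lengths))
  tibble(
    region = region_names,
    start = c(0L, head(ends, -1L)),
    end = ends
  )
}

#' Generate a synthetic rRNA operon family with planted clades
#'
#' Draws a random root operon, plants the (mutation-protected) universal
#' primer binding sites, mutates clade ancestors from the root and OTUs
#' from their ancestor — conserved genes at `gene_mut_rate`, ITS spacers
#' at `its_mut_rate`, i.i.d. substitutions to a uniform alternative base,
#' no indels (so all operons share one coordinate map). The OTU *record*
#' sequence is the ITS2 slice of its operon, emulating the pyrosequenced
#' ITS2 amplicon from which targets are screened and primers designed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `root` (list: `template_id`, `sequence`),
#'   `regions` (0-based half-open region map shared by all templates),
#'   `operons` (tibble: `template_id`, `clade_id`, `sequence`), `otus`
#'   (tibble: `otu_id`, `clade_id`, `sequence`, `total_reads`) and
#'   `otu_regions` (region map of the OTU records).
#' @export
generate_operon_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (sum(config$region_lengths) == 0) {
    abort("region lengths sum to 0", class = "darktaxa_validation_error")
  }
  regions <- region_map(config$region_lengths)
  len <- sum(config$region_lengths)
  with_seed(config$seed, {
    root <- random_dna(len)
    protect <- rep(FALSE, len)
    up <- config$universal_primers
    for (i in seq_len(nrow(up))) {
      site <- if (up$direction[i] == "forward") {
        up$sequence[i]
      } else {
        reverse_complement(up$sequence[i])
      }
      if (grepl("[^ACGT]", site)) next # degenerate oligos get no exact site
      g <- regions[regions$region == up$gene[i], ]
      pos <- g$start + up$site_offset[i] # 0-based
      stopifnot(pos + nchar(site) <= g$end)
      substr(root, pos + 1L, pos + nchar(site)) <- site
      protect[(pos + 1L):(pos + nchar(site))] <- TRUE
    }
    # per-position substitution probability by region class
    is_gene <- rep(
      regions$region %in% gene_regions,
      times = config$region_lengths
    )
    q_clade <- ifelse(
      is_gene,
      branch_q(config$gene_mut_rate, config$clade_depth),
      branch_q(config$its_mut_rate, config$clade_depth)
    )
    q_otu <- ifelse(
      is_gene,
      branch_q(config$gene_mut_rate, config$otu_depth),
      branch_q(config$its_mut_rate, config$otu_depth)
    )
    clade_ids <- sprintf("clade_%02d", seq_len(config$n_clades))
    ancestors <- vapply(
      clade_ids,
      function(cl) mutate_sequence(root, q_clade, protect),
      character(1)
    )
    otu_rows <- list()
    for (k in seq_len(config$n_clades)) {
      for (j in seq_len(config$otus_per_clade)) {
        i <- (k - 1L) * config$otus_per_clade + j
        otu_rows[[i]] <- tibble(
          otu_id = sprintf("OTU%03d", i),
          clade_id = clade_ids[k],
          operon = mutate_sequence(ancestors[k], q_otu, protect)
        )
      }
    }
    operons <- bind_rows(otu_rows)
    its2 <- regions[regions$region == "ITS2", ]
    otus <- operons |>
      mutate(
        sequence = substr(.data$operon, its2$start + 1L, its2$end),
        total_reads = rnbinom(n(), mu = 50, size = 1) + 1L
      ) |>
      select("otu_id", "clade_id", "sequence", "total_reads")
    list(
      root = list(template_id = "root", sequence = root),
      regions = regions,
      operons = operons |>
        rename(template_id = "otu_id") |>
        select("template_id", "clade_id", sequence = "operon"),
      otus = otus,
      otu_regions = tibble(
        region = "ITS2", start = 0L,
        end = its2$end - its2$start
      )
    )
  })
}

#' Generate named reference sequences
#'
#' Random ITS2-length sequences carrying Latin binomials, unrelated to the
#' synthetic operon family — the screening stage's stand-in for named
#' species.
#'
#' @param n Number of references.
#' @param length Sequence length in bases.
#' @param seed Integer seed.
#' @return A tibble with `ref_id`, `binomial`, `sequence`.
#' @export
generate_references <- function(n = 10, length = 250, seed = 1L) {
  with_seed(seed, {
    tibble(
      ref_id = sprintf("REF%03d", seq_len(n)),
      binomial = sprintf("Fungus speciosus%03d", seq_len(n)),
      sequence = vapply(seq_len(n), function(i) random_dna(length), character(1))
    )
  })
}

#' Construct a chimeric sequence
#'
#' Joins the first `breakpoint` bases of `seq_a` (0-based: `A[0:bp]`) to
#' the remainder of `seq_b` (`B[bp:]`) — the classic PCR chimera used as a
#' fixture for the overlap-based quality control.
#'
#' @param seq_a,seq_b DNA strings.
#' @param breakpoint Integer with `0 < breakpoint < min(len A, len B)`.
#' @return The chimeric DNA string.
#' @export
generate_chimera <- function(seq_a, seq_b, breakpoint) {
  nmin <- min(nchar(seq_a), nchar(seq_b))
  if (breakpoint <= 0 || breakpoint >= nmin) {
    abort(
      paste0("breakpoint must lie strictly inside both sequences (0, ", nmin, ")"),
      class = "darktaxa_validation_error"
    )
  }
  paste0(
    substr(seq_a, 1L, breakpoint),
    substr(seq_b, breakpoint + 1L, nchar(seq_b))
  )
}

#' Generate site metadata and a site-by-OTU occurrence matrix
#'
#' Site environments are drawn independently (MAT ~ U(-5, 28) degC, MAP ~
#' U(100, 4000) mm, pH ~ U(3, 8.5), log-normal soil C and P, fire time ~
#' U(0, 100) yr, categorical biome/region), and each OTU of clade *c* is
#' present at a site with probability
#' `max_occurrence_prob * exp(-(v - niche_mean)^2 / (2 niche_sd^2))`
#' evaluated at the site's value of the clade's focal variable
#' (`niche_sd = Inf` gives a flat niche).
#'
#' @param config A [sim_config()]; `env_model` must cover every clade in
#'   `truth`.
#' @param truth Tibble with `otu_id` and `clade_id` (as produced by
#'   [generate_operon_family()]).
#' @return A list with `occurrence` (long tibble `sample_id`, `otu_id`,
#'   `occurrence` in 0/1, complete over all pairs) and `sites` (metadata
#'   tibble).
#' @export
generate_occurrences <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  missing_clades <- setdiff(unique(truth$clade_id), config$env_model$clade_id)
  if (length(missing_clades)) {
    abort(
      paste0(
        "env_model does not cover clade(s): ",
        paste(missing_clades, collapse = ", ")
      ),
      class = "darktaxa_validation_error"
    )
  }
  with_seed(config$seed + 1L, {
    n <- config$n_sites
    sites <- tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      MAT = runif(n, -5, 28),
      MAP = runif(n, 100, 4000),
      pH = runif(n, 3, 8.5),
      soil_C = round(stats::rlnorm(n, log(2), 0.6), 3),
      soil_P = round(stats::rlnorm(n, log(20), 0.7), 2),
      fire_time = runif(n, 0, 100),
      biome = sample(
        c(
          "tundra", "boreal_forest", "temperate_forest", "grassland",
          "tropical_forest", "savanna"
        ), n,
        replace = TRUE
      ),
      region = sample(
        c(
          "Europe", "North_America", "Central_America", "South_America",
          "Africa", "North_Asia", "South_Asia", "Australia"
        ), n,
        replace = TRUE
      )
    )
    occ <- truth |>
      left_join(config$env_model, by = "clade_id") |>
      tidyr::crossing(sites["sample_id"]) |>
      left_join(sites, by = "sample_id")
    v <- vapply(
      seq_len(nrow(occ)),
      function(i) occ[[occ$variable[i]]][i],
      numeric(1)
    )
    p <- ifelse(
      is.infinite(occ$niche_sd),
      occ$max_occurrence_prob,
      occ$max_occurrence_prob *
        exp(-(v - occ$niche_mean)^2 / (2 * occ$niche_sd^2))
    )
    occ$occurrence <- rbinom(nrow(occ), 1L, p)
    list(
      occurrence = occ |>
        select("sample_id", "otu_id", "occurrence") |>
        arrange(.data$sample_id, .data$otu_id),
      sites = sites
    )
  })
}

#' Cut an operon into an overlapping sequencing read set
#'
#' Emulates the read structure the construct assembler consumes: a Sanger
#' 18S read running into the ITS, the pyrosequenced ITS2 fragment, and a
#' Sanger 28S read reaching back into the ITS2, each pair sharing
#' `overlap` bases.
#'
#' @param operon_seq Full operon sequence.
#' @param regions Region map (as from [generate_operon_family()]).
#' @param overlap Bases shared between consecutive reads. Default 60.
#' @return A tibble of read segments (`read_id`, `sequence`,
#'   `claimed_region`, `source`).
#' @export
operon_read_set <- function(operon_seq, regions, overlap = 60) {
  its2 <- regions[regions$region == "ITS2", ]
  len <- nchar(operon_seq)
  tibble(
    read_id = c("r18S", "rITS2", "r28S"),
    sequence = c(
      substr(operon_seq, 1L, its2$start + overlap),
      substr(operon_seq, its2$start + 1L, its2$end),
      substr(operon_seq, its2$end - overlap + 1L, len)
    ),
    claimed_region = c("SSU18S", "ITS", "LSU28S"),
    source = c("sanger", "pyrosequencing", "sanger")
  )
}
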