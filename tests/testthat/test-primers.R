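random_otus <- function(n, len = 200) {
  tibble::tibble(
    otu_id = sprintf("O%03d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) rand_dna(len), character(1))
  )
}

test_that("3'-decamer counts equal a brute-force substring scan", {
  set.seed(31)
  otus <- random_otus(30)
  dec <- "ACGTTGCACT"
  # plant the decamer verbatim in 5 OTUs and its reverse complement in 3
  for (i in 1:5) substr(otus$sequence[i], 50, 59) <- dec
  rc <- reverse_complement(dec)
  for (i in 6:8) substr(otus$sequence[i], 100, 109) <- rc
  cand <- paste0("GGTACA", dec) # candidate ending in the decamer
  expect_equal(three_prime_specificity(cand, otus), 8L)

  # brute-force oracle over all OTUs and strands
  brute <- sum(vapply(otus$sequence, function(s) {
    grepl(dec, s, fixed = TRUE) |
      grepl(dec, reverse_complement(s), fixed = TRUE)
  }, logical(1)))
  expect_equal(three_prime_specificity(cand, otus), brute)

  # absent decamer; and self-match of a candidate cut from its target
  expect_equal(three_prime_specificity("GGTACAAAAAAAAAAT", otus[9:20, ]), 0L)
  self_cand <- substr(otus$sequence[12], 21, 38)
  expect_gte(three_prime_specificity(self_cand, otus), 1L)
  expect_error(three_prime_specificity("ACGTACGT", otus),
    class = "darktaxa_validation_error"
  )
})

test_that("each criterion excludes its violator and admits a passer", {
  set.seed(32)
  template <- rand_dna(400)
  otus <- dplyr::bind_rows(
    tibble::tibble(otu_id = "self", sequence = template),
    random_otus(25, 400)
  )
  window <- c(0L, 400L)
  all_cand <- design_primers(template, otus, window, target_id = "t")
  expect_gt(nrow(all_cand), 0) # a compliant candidate exists
  top <- all_cand[1, ]
  ev <- evaluate_criteria(
    tibble::tibble(
      sequence = top$sequence, direction = top$direction,
      template_start = top$template_start, template_end = top$template_end
    ),
    otus, window
  )
  expect_true(ev$pass)

  # length violation: a 15-mer
  ev15 <- evaluate_criteria(
    tibble::tibble(
      sequence = substr(template, 101, 115), direction = "forward",
      template_start = 100L, template_end = 115L
    ),
    otus, window
  )
  expect_false(ev15$pass_length)
  expect_false(ev15$pass)

  # flank violation: 3' end 10 bases from the downstream boundary
  evfl <- evaluate_criteria(
    tibble::tibble(
      sequence = substr(template, 373, 390), direction = "forward",
      template_start = 372L, template_end = 390L
    ),
    otus, window
  )
  expect_equal(evfl$distance_to_flank, 10L)
  expect_false(evfl$pass_flank)

  # GC violation: a homopolymer
  evgc <- evaluate_criteria(
    tibble::tibble(
      sequence = strrep("A", 18), direction = "forward",
      template_start = 100L, template_end = 118L
    ),
    otus, window
  )
  expect_false(evgc$pass_gc)

  # Tm violation: search the enumeration for a GC-compliant hot oligo
  enum <- tidyr::crossing(len = 16:21, start = 30:340)
  enum$seq <- substring(template, enum$start + 1, enum$start + enum$len)
  tm <- melting_temperature(enum$seq)
  gc <- 100 * gc_fraction(enum$seq)
  hot <- which(tm > 58 & gc >= 33 & gc <= 62)[1]
  expect_false(is.na(hot))
  evtm <- evaluate_criteria(
    tibble::tibble(
      sequence = enum$seq[hot], direction = "forward",
      template_start = enum$start[hot],
      template_end = enum$start[hot] + enum$len[hot]
    ),
    otus, window
  )
  expect_true(evtm$pass_gc)
  expect_false(evtm$pass_tm)

  # specificity violation: plant a compliant candidate's decamer widely
  otus_planted <- otus
  dec <- substr(top$sequence, nchar(top$sequence) - 9, nchar(top$sequence))
  for (i in 2:21) substr(otus_planted$sequence[i], 11, 20) <- dec
  evsp <- evaluate_criteria(
    tibble::tibble(
      sequence = top$sequence, direction = top$direction,
      template_start = top$template_start, template_end = top$template_end
    ),
    otus_planted, window
  )
  expect_gte(evsp$three_prime_hits, 20L)
  expect_false(evsp$pass_specificity)

  # a candidate outside the annotated window is an error
  expect_error(
    evaluate_criteria(
      tibble::tibble(
        sequence = strrep("A", 18), direction = "forward",
        template_start = 395L, template_end = 413L
      ),
      otus, window
    ),
    class = "darktaxa_validation_error"
  )
})

test_that("tightening any criterion bound never enlarges the passing set", {
  set.seed(33)
  template <- rand_dna(300)
  otus <- dplyr::bind_rows(
    tibble::tibble(otu_id = "self", sequence = template), random_otus(15, 300)
  )
  base <- design_primers(template, otus, target_id = "t")
  key <- function(x) paste(x$sequence, x$direction)
  tighter <- list(
    primer_config(tm_min = 55, tm_max = 57),
    primer_config(gc_min = 40, gc_max = 55),
    primer_config(len_min = 18, len_max = 20),
    primer_config(specificity_max = 2),
    primer_config(flank_min = 40)
  )
  for (cfg in tighter) {
    sub <- design_primers(template, otus, config = cfg, target_id = "t")
    expect_true(all(key(sub) %in% key(base)))
  }
})

test_that("design matches an exhaustive enumeration oracle", {
  set.seed(34)
  template <- rand_dna(120)
  otus <- dplyr::bind_rows(
    tibble::tibble(otu_id = "self", sequence = template), random_otus(10, 120)
  )
  got <- design_primers(template, otus, target_id = "t")

  # test-side enumeration from first principles
  oracle <- list()
  for (len in 16:21) {
    for (start in 0:(120 - len)) {
      for (dir in c("forward", "reverse")) {
        slice <- substr(template, start + 1, start + len)
        oligo <- if (dir == "forward") slice else reverse_complement(slice)
        tm <- melting_temperature(oligo)
        gc <- 100 * gc_fraction(oligo)
        dec <- substr(oligo, len - 9, len)
        hits <- sum(vapply(otus$sequence, function(s) {
          grepl(dec, s, fixed = TRUE) ||
            grepl(dec, reverse_complement(s), fixed = TRUE)
        }, logical(1)))
        flank <- min(start, 120 - (start + len))
        if (tm >= 54 && tm <= 58 && gc >= 33 && gc <= 62 &&
          hits < 20 && flank > 20) {
          oracle[[length(oracle) + 1L]] <- paste(oligo, dir, start)
        }
      }
    }
  }
  expect_setequal(
    paste(got$sequence, got$direction, got$template_start),
    unlist(oracle)
  )
})

test_that("design output ignores OTU dataset order and member order", {
  set.seed(35)
  anc <- rand_dna(250)
  members <- c(mutate_at(anc, 0.01), mutate_at(anc, 0.01))
  otus <- dplyr::bind_rows(
    tibble::tibble(otu_id = c("m1", "m2"), sequence = members),
    random_otus(12, 250)
  )
  a <- design_primers(members, otus, target_id = "t")
  b <- design_primers(rev(members), otus[sample(nrow(otus)), ], target_id = "t")
  expect_gt(nrow(a), 0)
  expect_equal(a, b)
  # grouped candidates are identical across both members by construction
  for (i in seq_len(nrow(a))) {
    s1 <- substr(members[1], a$template_start[i] + 1, a$template_end[i])
    s2 <- substr(members[2], a$template_start[i] + 1, a$template_end[i])
    expect_identical(s1, s2)
  }
})

test_that("degenerate windows yield no candidates, short windows error", {
  otus <- random_otus(3, 60)
  expect_equal(nrow(design_primers(strrep("A", 60), otus, target_id = "t")), 0)
  expect_error(design_primers(strrep("ACGT", 3), otus, target_id = "t"),
    class = "darktaxa_validation_error"
  )
})

test_that("universal pairing honours the orientation contract", {
  cand <- tibble::tibble(
    target_id = "t", direction = c("reverse", "forward"),
    sequence = c("ACGTACGTACGTACGTAC", "TGCATGCATGCATGCATG"),
    template_start = c(30L, 60L), template_end = c(48L, 78L),
    length = 18L, Tm = 52, GC_pct = 50, three_prime_hits = 1L,
    distance_to_flank = 30L, rank = 1L
  )
  pairs <- pair_with_universal(cand)
  rev_pairs <- pairs[pairs$direction == "reverse", ]
  fwd_pairs <- pairs[pairs$direction == "forward", ]
  expect_setequal(rev_pairs$universal_partner, c("NS5a", "NS7a"))
  expect_equal(unique(rev_pairs$amplified_gene), "SSU18S")
  expect_setequal(fwd_pairs$universal_partner, c("TW13", "LR5"))
  expect_equal(unique(fwd_pairs$amplified_gene), "LSU28S")

  expect_error(
    pair_with_universal(cand[2, ], universal_names = "NS5a"),
    class = "darktaxa_validation_error"
  )
  broken <- default_universal_primers()
  broken <- broken[broken$name != "NS5a", ]
  expect_error(pair_with_universal(cand, universal = broken),
    class = "darktaxa_validation_error"
  )
})

test_that("in-silico PCR finds convergent products and flags repeats", {
  set.seed(36)
  spec <- "TGCAGGTCAATCGCAGTC" # forward specific primer
  tw13 <- default_universal_primers()
  tw13_seq <- tw13$sequence[tw13$name == "TW13"]
  mk <- function(...) paste0(...)
  template1 <- mk(
    rand_dna(40), spec, rand_dna(300), reverse_complement(tw13_seq),
    rand_dna(30)
  )
  template2 <- rand_dna(nchar(template1)) # lacks the specific site
  template3 <- mk(
    rand_dna(20), spec, rand_dna(100), spec, rand_dna(200),
    reverse_complement(tw13_seq), rand_dna(30)
  )
  pairs <- tibble::tibble(
    target_id = "t", direction = "forward", primer_seq = spec,
    universal_partner = "TW13", universal_seq = tw13_seq,
    amplified_gene = "LSU28S"
  )
  operons <- tibble::tibble(
    template_id = c("own", "other", "double"),
    sequence = c(template1, template2, template3)
  )
  amp <- insilico_pcr(pairs, operons)
  own <- amp[amp$template_id == "own", ]
  expect_equal(nrow(own), 1L)
  expect_false(own$unspecific)
  # the amplicon spans from the specific site through the universal site
  expect_equal(own$start, 40L)
  expect_equal(own$end, 40L + 18L + 300L + 18L)
  expect_equal(nrow(amp[amp$template_id == "other", ]), 0L)
  dbl <- amp[amp$template_id == "double", ]
  expect_equal(nrow(dbl), 2L)
  expect_true(all(dbl$unspecific))
})
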