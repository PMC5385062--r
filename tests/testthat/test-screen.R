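make_refs <- function(seqs) {
  tibble::tibble(
    ref_id = sprintf("R%02d", seq_along(seqs)),
    binomial = sprintf("Genus species%02d", seq_along(seqs)),
    sequence = seqs
  )
}

test_that("screening excludes identifiable OTUs and keeps dark ones", {
  set.seed(21)
  ref_seq <- rand_dna(200)
  otus <- tibble::tibble(
    otu_id = c("known", "dark"),
    sequence = c(ref_seq, mutate_at(ref_seq, 0.35))
  )
  refs <- make_refs(c(ref_seq, rand_dna(200)))
  kept <- screen_unidentifiable(otus, refs, threshold = 0.80)
  expect_equal(kept$otu_id, "dark")
  expect_equal(kept$best_ref_id, "R01")

  # threshold boundary: any mismatching OTU is retained at threshold 1
  kept_all <- screen_unidentifiable(otus, refs, threshold = 1.0)
  expect_true("dark" %in% kept_all$otu_id)
  expect_false("known" %in% kept_all$otu_id)

  expect_error(
    screen_unidentifiable(otus, make_refs(character(0))),
    class = "darktaxa_validation_error"
  )
})

test_that("single linkage chains borderline pairs transitively", {
  # A-B and B-C linkable, A-C not: one connected cluster of three
  set.seed(22)
  a <- rand_dna(200)
  b <- mutate_at(a, 0.10)
  c_ <- mutate_at(b, 0.10)
  otus <- tibble::tibble(otu_id = c("A", "B", "C"), sequence = c(a, b, c_))
  ab <- pairwise_identity(a, b)$identity
  bc <- pairwise_identity(b, c_)$identity
  ac <- pairwise_identity(a, c_)$identity
  thr <- (max(ac, 0.5) + min(ab, bc)) / 2 # between the weak and strong links
  expect_true(ab >= thr && bc >= thr && ac < thr)
  cl <- single_linkage_cluster(otus, threshold = thr)
  expect_equal(unique(cl$cluster_id), "C001")

  # all pairs below threshold: all singletons
  cl2 <- single_linkage_cluster(otus, threshold = 0.999)
  expect_equal(length(unique(cl2$cluster_id)), 3L)
})

test_that("clustering is canonical under input permutation", {
  set.seed(23)
  fam <- toy_family()
  cl1 <- single_linkage_cluster(fam)
  cl2 <- single_linkage_cluster(fam[sample(nrow(fam)), ])
  expect_equal(cl1, cl2)
})

test_that("lowering the threshold never increases the cluster count", {
  set.seed(24)
  fam <- toy_family(n_per_clade = 3, div_between = 0.25, div_within = 0.08)
  n_clusters <- vapply(
    c(0.95, 0.9, 0.85, 0.8, 0.7, 0.5),
    function(t) {
      length(unique(single_linkage_cluster(fam, threshold = t)$cluster_id))
    },
    integer(1)
  )
  expect_true(all(diff(n_clusters) <= 0))
})

test_that("insufficient coverage blocks linkage regardless of identity", {
  set.seed(25)
  s <- rand_dna(80) # identical 80-mers: identity 1 but overlap 80 < 100
  otus <- tibble::tibble(otu_id = c("A", "B"), sequence = c(s, s))
  cl <- single_linkage_cluster(otus, threshold = 0.8, min_overlap = 100)
  expect_equal(length(unique(cl$cluster_id)), 2L)
  cl2 <- single_linkage_cluster(otus, threshold = 0.8, min_overlap = 60)
  expect_equal(length(unique(cl2$cluster_id)), 1L)
})

test_that("target selection groups near-identical OTUs and splits others", {
  set.seed(26)
  base <- rand_dna(200)
  near <- base
  substr(near, 11, 14) <- paste(
    vapply(
      strsplit(substr(base, 11, 14), "")[[1]],
      function(b) setdiff(c("A", "C", "G", "T"), b)[1], character(1)
    ),
    collapse = ""
  ) # 4/200 differences: identity ~0.98 > 0.95
  far <- mutate_at(base, 0.10) # ~0.90: same cluster, below grouping bound
  otus <- tibble::tibble(
    otu_id = c("O1", "O2", "O3"),
    sequence = c(base, near, far),
    total_reads = c(5, 50, 10)
  )
  cl <- single_linkage_cluster(otus, threshold = 0.80)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  tg <- select_targets(cl, otus)
  expect_equal(sort(tg$type), c("group", "individual"))
  expect_equal(tg$members[tg$type == "group"][[1]], c("O1", "O2"))
  expect_equal(tg$members[tg$type == "individual"][[1]], "O3")

  # two OTUs at ~90% identity in one cluster: two individual targets
  otus2 <- otus[c(1, 3), ]
  tg2 <- select_targets(single_linkage_cluster(otus2, threshold = 0.80), otus2)
  expect_equal(tg2$type, c("individual", "individual"))
})

test_that("major clusters are always covered and abundance caps selection", {
  set.seed(27)
  anc <- rand_dna(200)
  otus <- tibble::tibble(
    otu_id = sprintf("O%02d", 1:12),
    sequence = vapply(1:12, function(i) mutate_at(anc, 0.04), character(1)),
    total_reads = c(1, 3, 99, rep(2, 9))
  )
  cl <- single_linkage_cluster(otus, threshold = 0.80)
  expect_equal(unique(cl$cluster_size), 12L)
  tg <- select_targets(cl, otus, major_cluster_size = 10)
  expect_true(all(tg$major))
  expect_gte(nrow(tg), 1L) # the major cluster contributes a target

  # capping individual targets keeps the most abundant member
  tg_cap <- select_targets(cl, otus,
    group_identity = 0.999,
    max_individual_per_cluster = 1
  )
  singles <- tg_cap$members[tg_cap$type == "individual"]
  if (length(singles)) {
    expect_equal(singles[[1]], "O03")
  }
})
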