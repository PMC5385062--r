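toy_sites <- function(ph) {
  n <- length(ph)
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    MAT = seq(0, 20, length.out = n), MAP = 1000, pH = ph,
    soil_C = 2, soil_P = 20, fire_time = 50,
    biome = rep_len(c("tundra", "savanna"), n),
    region = rep_len(c("Europe", "Africa"), n)
  )
}

occ_rows <- function(sample_id, otu_id, occurrence) {
  tibble::tibble(sample_id = sample_id, otu_id = otu_id, occurrence = occurrence)
}

test_that("group samples carry summed occurrence weights per site", {
  sites <- toy_sites(c(4, 5, 6))
  occ <- occ_rows(
    c("S01", "S01", "S02"), c("O1", "O2", "O1"), c(1, 1, 0)
  )
  g <- group_env_sample(occ, sites, c("O1", "O2"), "pH")
  expect_equal(g$value, 4)
  expect_equal(g$weight, 2)

  expect_error(
    group_env_sample(occ_rows("S01", "O1", 0), sites, "O1", "pH"),
    class = "darktaxa_nd"
  )

  # sites with a missing variable value are dropped for that variable only
  sites$pH[1] <- NA
  occ2 <- occ_rows(c("S01", "S02"), "O1", c(1, 1))
  expect_equal(group_env_sample(occ2, sites, "O1", "pH")$value, 5)
  expect_equal(nrow(group_env_sample(occ2, sites, "O1", "MAT")), 2L)
})

test_that("the null sample is all non-missing site values", {
  sites <- toy_sites(c(4, 5, 6))
  expect_equal(null_env_sample(sites, "pH"), c(4, 5, 6))
  sites$pH[2] <- NA
  expect_equal(null_env_sample(sites, "pH"), c(4, 6))
  expect_error(null_env_sample(sites[1, ], "pH"),
    class = "darktaxa_validation_error"
  )
})

test_that("weighted SD equals the expanded-multiset population SD", {
  expect_equal(weighted_sd(c(2, 4), c(1, 1)), 1)
  expect_equal(weighted_sd(c(7, 7, 7)), 0)
  set.seed(51)
  for (i in 1:10) {
    v <- rnorm(6)
    w <- sample(1:4, 6, replace = TRUE)
    expanded <- rep(v, w)
    expect_equal(
      weighted_sd(v, w),
      sqrt(mean((expanded - mean(expanded))^2))
    )
  }
})

test_that("Levene W matches the car oracle to 1e-6 and is symmetric", {
  skip_if_not_installed("car")
  set.seed(52)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    ours <- levene_test(a, b)
    oracle <- car::leveneTest(
      c(a, b), factor(rep(c("a", "b"), c(length(a), length(b)))),
      center = mean
    )
    expect_equal(ours$statistic, oracle$`F value`[1], tolerance = 1e-6)
    expect_equal(ours$p_value, oracle$`Pr(>F)`[1], tolerance = 1e-6)
    swapped <- levene_test(b, a)
    expect_equal(ours$statistic, swapped$statistic)
    expect_equal(ours$p_value, swapped$p_value)
  }
})

test_that("degenerate Levene inputs follow the stated conventions", {
  same <- c(1, 2, 3, 4, 5)
  res <- levene_test(same, same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res2 <- levene_test(c(3, 3, 3), c(5, 5, 5))
  expect_equal(res2$p_value, 1)
})

test_that("narrowness requires both the SD ratio and the Levene test", {
  set.seed(53)
  ph <- runif(200, 3, 8.5)
  sites <- toy_sites(ph)
  # narrow group: occupies only sites in a thin pH slab
  narrow_sites <- sites$sample_id[abs(ph - 5.75) < 0.4]
  occ <- dplyr::bind_rows(
    occ_rows(narrow_sites, "N1", 1),
    occ_rows(sites$sample_id, "F1", 1) # flat group occupies everything
  )
  groups <- tibble::tibble(
    otu_id = c("N1", "F1"), group_id = c("narrow", "flat")
  )
  res <- niche_narrowness(occ, sites, groups, variables = "pH")
  narrow <- res[res$group_id == "narrow", ]
  flat <- res[res$group_id == "flat", ]
  expect_true(narrow$significant)
  expect_gt(narrow$sd_ratio, 2)
  expect_equal(narrow$grade, "***")
  expect_false(flat$significant)
  expect_equal(flat$grade, "")

  # conjunction: a strong Levene p cannot rescue a weak SD ratio
  res_strict <- niche_narrowness(occ, sites, groups,
    variables = "pH", sd_ratio_min = narrow$sd_ratio + 1
  )
  expect_false(res_strict$significant[res_strict$group_id == "narrow"])

  # zero-occurrence groups are reported as nd, not dropped
  groups_nd <- dplyr::bind_rows(
    groups, tibble::tibble(otu_id = "Z1", group_id = "zero")
  )
  occ_nd <- dplyr::bind_rows(occ, occ_rows("S001", "Z1", 0))
  res_nd <- niche_narrowness(occ_nd, sites, groups_nd, variables = "pH")
  expect_true(res_nd$nd[res_nd$group_id == "zero"])
  expect_equal(res_nd$grade[res_nd$group_id == "zero"], "nd")
})

test_that("narrowness is invariant under affine rescaling", {
  set.seed(54)
  ph <- runif(100, 3, 8.5)
  sites <- toy_sites(ph)
  keep <- sites$sample_id[abs(ph - 5) < 0.8]
  occ <- occ_rows(keep, "O1", 1)
  groups <- tibble::tibble(otu_id = "O1", group_id = "g")
  r1 <- niche_narrowness(occ, sites, groups, variables = "pH")
  sites2 <- sites
  sites2$pH <- -3.7 * sites$pH + 11
  sites2$pH <- pmax(pmin(sites2$pH, 14), 0) # keep the validator happy
  sites2$pH <- -0.5 * sites$pH + 10
  r2 <- niche_narrowness(occ, sites2, groups, variables = "pH")
  expect_equal(r1$sd_ratio, r2$sd_ratio, tolerance = 1e-12)
  expect_equal(r1$levene_W, r2$levene_W, tolerance = 1e-9)
})

test_that("bias p-values have permutation granularity and sane nulls", {
  set.seed(55)
  ph <- runif(60, 3, 8.5)
  sites <- toy_sites(ph)
  occ <- occ_rows(sites$sample_id, "O1", rbinom(60, 1, 0.5))
  groups <- tibble::tibble(otu_id = "O1", group_id = "g")
  res <- categorical_bias_test(occ, sites, groups, "biome", n_perm = 999)
  expect_true(res$p_value >= 1 / 1000 && res$p_value <= 1)
  expect_equal(res$p_value * 1000, round(res$p_value * 1000))

  # all occurrences concentrated in one of the categories: tiny p
  conc <- occ_rows(sites$sample_id[sites$biome == "tundra"], "O1", 1)
  res2 <- categorical_bias_test(conc, sites, groups, "biome", n_perm = 999)
  expect_equal(res2$p_value, 0.001)

  # single-category metadata: p = 1 by convention
  sites1 <- sites
  sites1$biome <- "tundra"
  res3 <- categorical_bias_test(occ, sites1, groups, "biome", n_perm = 99)
  expect_equal(res3$p_value, 1)
})

test_that("the cross-validation harness honours its contracts", {
  set.seed(56)
  n <- 60
  data <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:n),
    x1 = rnorm(n), x2 = rnorm(n)
  )
  y <- 2 * data$x1 - data$x2 + rnorm(n, sd = 0.1)
  names(y) <- data$sample_id

  # oracle predictor that memorises the answer: harness must report 1
  oracle <- list(
    fit = function(data, yy) NULL,
    predict = function(model, newdata) unname(y[newdata$sample_id]),
    label = "oracle"
  )
  res <- cv_r2(data, unname(y), oracle, k = 10, repeats = 3)
  expect_equal(res$r2, rep(1, 3))

  # training-mean predictor: pooled out-of-fold R2 is non-positive
  res_mean <- cv_r2(data, unname(y), predictor_mean(), k = 10, repeats = 10)
  expect_true(all(res_mean$r2 <= 0))

  # an informative model scores clearly above the mean baseline
  res_lm <- cv_r2(data, unname(y), predictor_lm(), k = 10, repeats = 10)
  expect_gt(mean(res_lm$r2), 0.9)

  # determinism under a fixed RNG state
  set.seed(99)
  a <- cv_r2(data, unname(y), predictor_lm(), k = 5, repeats = 4)
  set.seed(99)
  b <- cv_r2(data, unname(y), predictor_lm(), k = 5, repeats = 4)
  expect_identical(a$r2, b$r2)

  expect_error(cv_r2(data, unname(y), predictor_mean(), k = 100),
    class = "darktaxa_validation_error"
  )
  gl <- glance(res_lm)
  expect_equal(gl$repeats, 10)
  expect_equal(nrow(tidy(res_lm)), 10)
})

test_that("niche histograms conserve weight and concentrate as planted", {
  # conservation on a toy case
  sites <- toy_sites(c(4, 4.5, 5, 6, 7, 8))
  occ <- occ_rows(c("S01", "S02", "S03"), "O1", c(2, 3, 5))
  h <- niche_histogram(occ, sites, "O1", "pH", bins = 4)
  expect_equal(sum(h$group_weight), 10)
  expect_equal(sum(h$null_count), 6)
  expect_error(
    niche_histogram(occ, sites, "O1", "pH", bins = 1),
    class = "darktaxa_validation_error"
  )

  # planted narrow niche: most weight falls in the 2 bins flanking the
  # niche mean (edges aligned so 5.75 is a bin boundary); averaged over
  # seeds because single-draw weight totals are small
  edges <- seq(3, 8.5, by = 0.55)
  fracs <- vapply(1:20, function(s) {
    cfg <- sim_config(
      seed = 600 + s, n_clades = 1, otus_per_clade = 2, n_sites = 200,
      env_model = tibble::tibble(
        clade_id = "clade_01", variable = "pH", niche_mean = 5.75,
        niche_sd = 0.25 * (8.5 - 3) / sqrt(12), max_occurrence_prob = 0.8
      )
    )
    truth <- tibble::tibble(
      otu_id = c("O1", "O2"), clade_id = "clade_01"
    )
    occ_s <- generate_occurrences(cfg, truth)
    hh <- niche_histogram(
      occ_s$occurrence, occ_s$sites, truth$otu_id, "pH",
      bins = edges
    )
    central <- hh$bin_left >= 5.75 - 0.55 - 1e-9 &
      hh$bin_right <= 5.75 + 0.55 + 1e-9
    sum(hh$group_weight[central]) / sum(hh$group_weight)
  }, numeric(1))
  expect_gte(mean(fracs), 0.8)
})
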