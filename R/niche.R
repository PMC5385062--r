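#' Occurrence-weighted environmental sample for a group
#'
#' Returns the values of an environmental variable at the sites where the
#' group occurs, each value weighted by the summed occurrences of the
#' group's member OTUs at that site. Sites with a missing value of the
#' variable are dropped from analyses of that variable only.
#'
#' @param occurrence Long occurrence tibble (`sample_id`, `otu_id`,
#'   `occurrence`).
#' @param sites Site metadata tibble.
#' @param members Character vector of member OTU ids.
#' @param variable Name of the environmental variable.
#' @return A tibble with `sample_id`, `value`, `weight` (weight > 0).
#'   A group with zero occurrences raises a condition of class
#'   `darktaxa_nd` ("not determined").
#' @export
group_env_sample <- function(occurrence, sites, members, variable) {
  if (!variable %in% names(sites)) {
    abort(paste0("variable not in site metadata: ", variable),
      class = "darktaxa_validation_error"
    )
  }
  w <- occurrence |>
    filter(.data$otu_id %in% members) |>
    group_by(.data$sample_id) |>
    summarise(weight = sum(.data$occurrence), .groups = "drop") |>
    filter(.data$weight > 0)
  out <- w |>
    left_join(sites[, c("sample_id", variable)], by = "sample_id") |>
    rename(value = dplyr::all_of(variable)) |>
    filter(!is.na(.data$value)) |>
    select("sample_id", "value", "weight")
  if (nrow(out) == 0L) {
    abort("group has no occurrences with non-missing values: nd",
      class = "darktaxa_nd"
    )
  }
  out
}

#' Null environmental sample
#'
#' All non-missing site values of a variable, unweighted — the null
#' distribution of site conditions a group's occurrences are compared to.
#'
#' @inheritParams group_env_sample
#' @return Numeric vector of site values.
#' @export
null_env_sample <- function(sites, variable) {
  if (!variable %in% names(sites)) {
    abort(paste0("variable not in site metadata: ", variable),
      class = "darktaxa_validation_error"
    )
  }
  v <- sites[[variable]]
  v <- v[!is.na(v)]
  if (length(v) < 2L) {
    abort("fewer than 2 non-missing values",
      class = "darktaxa_validation_error"
    )
  }
  v
}

#' Frequency-weighted population standard deviation
#'
#' Weights act as repeat counts: the result equals the population SD of
#' the multiset in which each value is repeated `weight` times.
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights with a positive sum (default: all
#'   1).
#' @return A non-negative number; 0 for a single distinct value.
#' @export
weighted_sd <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights))
  if (sum(weights) <= 0) {
    abort("weights must have a positive sum",
      class = "darktaxa_validation_error"
    )
  }
  m <- sum(weights * values) / sum(weights)
  sqrt(sum(weights * (values - m)^2) / sum(weights))
}

#' Levene test for homogeneity of variances (two samples)
#'
#' Classic Levene W on absolute deviations from the group centre (mean by
#' default; median gives the Brown-Forsythe variant), with the p-value
#' from the F distribution on (1, nA + nB - 2) degrees of freedom. Two
#' samples with zero within-group deviation give p = 1 by convention.
#'
#' @param sample_a,sample_b Numeric vectors with at least 2 values each.
#' @param center `"mean"` (classic) or `"median"` (Brown-Forsythe).
#' @return A one-row tibble: `statistic` (W), `p_value`, `df1`, `df2`,
#'   `center`.
#' @export
levene_test <- function(sample_a, sample_b, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    abort("each sample needs at least 2 values",
      class = "darktaxa_validation_error"
    )
  }
  cfun <- if (center == "mean") mean else stats::median
  z <- list(abs(sample_a - cfun(sample_a)), abs(sample_b - cfun(sample_b)))
  ni <- lengths(z)
  nn <- sum(ni)
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / nn
  num <- (nn - 2) * sum(ni * (zbar_i - zbar)^2)
  den <- 1 * sum((unlist(z) - rep(zbar_i, ni))^2)
  if (den == 0) {
    w <- if (num == 0) 0 else Inf
    p <- if (num == 0) 1 else 0
  } else {
    w <- num / den
    p <- stats::pf(w, 1, nn - 2, lower.tail = FALSE)
  }
  tibble(
    statistic = w, p_value = p, df1 = 1L, df2 = nn - 2L, center = center
  )
}

star_grade <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Niche-narrowness test for groups of OTUs
#'
#' A group's niche along a variable is "significantly narrower than
#' expected" if (i) the SD of the null distribution of site conditions
#' exceeds the occurrence-weighted SD of the group's distribution more
#' than `sd_ratio_min`-fold and (ii) the Levene test between the null
#' values and the weight-expanded group values is significant at `alpha`.
#' Significant results carry a star grade from the Levene p-value
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001). Groups with zero
#' occurrences are reported as not determined (`nd = TRUE`).
#'
#' @param occurrence Long occurrence tibble.
#' @param sites Site metadata tibble.
#' @param groups Tibble mapping `otu_id` to `group_id`.
#' @param variables Environmental variables to test. Defaults to the six
#'   predictors `MAT`, `MAP`, `pH`, `soil_C`, `soil_P`, `fire_time`.
#' @param alpha Levene significance level. Default 0.05.
#' @param sd_ratio_min Required fold-excess of the null SD. Default 2.
#' @param center Levene centring, see [levene_test()].
#' @return A tibble of class `niche_result`: one row per group x
#'   variable with `n_sites_group`, `sd_null`, `sd_group`, `sd_ratio`,
#'   `levene_W`, `levene_p`, `significant`, `grade`, `nd`.
#' @export
niche_narrowness <- function(occurrence, sites, groups,
                             variables = site_numeric_cols,
                             alpha = 0.05, sd_ratio_min = 2,
                             center = "mean") {
  rows <- list()
  for (gid in sort(unique(groups$group_id))) {
    members <- groups$otu_id[groups$group_id == gid]
    for (v in variables) {
      null_v <- null_env_sample(sites, v)
      sd_null <- weighted_sd(null_v)
      grp <- tryCatch(
        group_env_sample(occurrence, sites, members, v),
        darktaxa_nd = function(e) NULL
      )
      if (is.null(grp)) {
        rows[[length(rows) + 1L]] <- tibble(
          group_id = gid, variable = v, n_sites_group = 0L,
          sd_null = sd_null, sd_group = NA_real_, sd_ratio = NA_real_,
          levene_W = NA_real_, levene_p = NA_real_,
          significant = NA, grade = "nd", nd = TRUE
        )
        next
      }
      sd_group <- weighted_sd(grp$value, grp$weight)
      expanded <- rep(grp$value, grp$weight)
      if (length(expanded) < 2L) {
        lw <- tibble(statistic = NA_real_, p_value = NA_real_)
      } else {
        lw <- levene_test(null_v, expanded, center = center)
      }
      ratio <- if (sd_group > 0) sd_null / sd_group else Inf
      sig <- isTRUE(ratio > sd_ratio_min && !is.na(lw$p_value) &&
        lw$p_value < alpha)
      rows[[length(rows) + 1L]] <- tibble(
        group_id = gid, variable = v, n_sites_group = nrow(grp),
        sd_null = sd_null, sd_group = sd_group, sd_ratio = ratio,
        levene_W = lw$statistic, levene_p = lw$p_value,
        significant = sig,
        grade = if (sig) star_grade(lw$p_value) else "",
        nd = FALSE
      )
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("niche_result", class(out))
  out
}

# G statistic of observed category weights against site-frequency
# proportional expectation; zero-observation categories contribute 0.
g_statistic <- function(obs, expected) {
  keep <- obs > 0
  2 * sum(obs[keep] * log(obs[keep] / expected[keep]))
}

#' Permutation test for categorical (biome/region) bias
#'
#' Tests whether a group's occurrences are biased across the levels of a
#' categorical site factor. The statistic is the G statistic of observed
#' versus expected (site-frequency-proportional) category weights; the
#' null is generated by permuting site labels (equivalently, the site
#' weight vector), and `p = (1 + #\{permuted >= observed\}) /
#' (n_perm + 1)`.
#'
#' @inheritParams niche_narrowness
#' @param factor `"biome"` or `"region"`.
#' @param n_perm Number of permutations. Default 999.
#' @return A tibble with one row per group: `group_id`, `factor`,
#'   `statistic`, `p_value`, `n_perm`. Results depend on the current RNG
#'   state; set a seed for reproducibility.
#' @export
categorical_bias_test <- function(occurrence, sites, groups,
                                  factor = c("biome", "region"),
                                  n_perm = 999) {
  factor <- match.arg(factor)
  f <- sites[[factor]]
  keep <- !is.na(f)
  f <- base::factor(f[keep])
  site_ids <- sites$sample_id[keep]
  cat_share <- as.vector(table(f)) / length(f)
  mm <- if (nlevels(f) >= 2L) stats::model.matrix(~ 0 + f) else NULL
  rows <- list()
  for (gid in sort(unique(groups$group_id))) {
    members <- groups$otu_id[groups$group_id == gid]
    w_tbl <- occurrence |>
      filter(.data$otu_id %in% members) |>
      group_by(.data$sample_id) |>
      summarise(weight = sum(.data$occurrence), .groups = "drop")
    w <- setNames(rep(0, length(site_ids)), site_ids)
    w[w_tbl$sample_id[w_tbl$sample_id %in% site_ids]] <-
      w_tbl$weight[w_tbl$sample_id %in% site_ids]
    if (sum(w) == 0) {
      abort(paste0("group ", gid, " has no occurrences: nd"),
        class = "darktaxa_nd"
      )
    }
    if (nlevels(f) < 2L) {
      rows[[length(rows) + 1L]] <- tibble(
        group_id = gid, factor = factor, statistic = NA_real_,
        p_value = 1, n_perm = as.integer(n_perm)
      )
      next
    }
    expected <- sum(w) * cat_share
    obs <- as.vector(crossprod(mm, w))
    g_obs <- g_statistic(obs, expected)
    perm_w <- replicate(n_perm, sample(w))
    perm_counts <- crossprod(mm, perm_w) # categories x n_perm
    g_perm <- apply(perm_counts, 2, g_statistic, expected = expected)
    p <- (1 + sum(g_perm >= g_obs)) / (n_perm + 1)
    rows[[length(rows) + 1L]] <- tibble(
      group_id = gid, factor = factor, statistic = g_obs,
      p_value = p, n_perm = as.integer(n_perm)
    )
  }
  bind_rows(rows)
}

#' Repeated k-fold cross-validated R-squared
#'
#' Wraps any predictor honouring a fit-then-predict contract in a
#' repeated k-fold cross-validation harness. Per repeat, sites are
#' randomly partitioned into `k` folds; the model is trained on k-1 folds
#' and predicts the held-out fold; R2 for the repeat is computed on the
#' pooled out-of-fold predictions as `1 - SSE/SST` (SST about the overall
#' mean of `y`).
#'
#' @param data A data frame of site predictors (rows = sites).
#' @param y Numeric response (e.g. a group's per-site summed occurrence).
#' @param predictor A list with functions `fit(data, y)` and
#'   `predict(model, newdata)`; see [predictor_lm()], [predictor_mean()],
#'   [predictor_rf()].
#' @param k Number of folds (`k <= n`). Default 10.
#' @param repeats Number of repeats. Default 100.
#' @return An object of class `cv_r2` with per-repeat R2 values; see
#'   [tidy.cv_r2()] and [glance.cv_r2()]. Uses the current RNG state; set
#'   a seed for reproducibility.
#' @export
cv_r2 <- function(data, y, predictor = predictor_lm(), k = 10,
                  repeats = 100) {
  n <- nrow(data)
  stopifnot(length(y) == n)
  if (k > n) {
    abort("k must not exceed the number of sites",
      class = "darktaxa_validation_error"
    )
  }
  sst <- sum((y - mean(y))^2)
  r2 <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- sample(rep(seq_len(k), length.out = n))
    pred <- numeric(n)
    for (j in seq_len(k)) {
      test <- fold == j
      model <- predictor$fit(data[!test, , drop = FALSE], y[!test])
      pred[test] <- predictor$predict(model, data[test, , drop = FALSE])
    }
    r2[r] <- 1 - sum((y - pred)^2) / sst
  }
  structure(
    list(
      r2 = r2, k = k, repeats = repeats, n = n,
      predictor = predictor$label %||% "custom"
    ),
    class = "cv_r2"
  )
}

#' @export
print.cv_r2 <- function(x, ...) {
  cat(
    "<cv_r2>", x$predictor, ":", x$repeats, "repeats of", x$k,
    "folds on", x$n, "sites\n"
  )
  cat(sprintf(
    "  R2-cv = %.3f (SD %.3f)\n", mean(x$r2), stats::sd(x$r2)
  ))
  invisible(x)
}

#' Pluggable predictors for the cross-validation harness
#'
#' `predictor_lm()` fits an ordinary linear model on all numeric
#' predictor columns; `predictor_mean()` always predicts the training
#' mean (a null baseline whose pooled out-of-fold R2 is at most 0);
#' `predictor_rf()` wraps a random forest (requires the randomForest
#' package).
#'
#' @return A list with `fit(data, y)`, `predict(model, newdata)` and a
#'   `label`, as expected by [cv_r2()].
#' @export
predictor_lm <- function() {
  list(
    fit = function(data, y) {
      df <- numeric_predictors(data)
      stats::lm(y ~ ., data = cbind(df, y = y))
    },
    predict = function(model, newdata) {
      unname(stats::predict(model, newdata = numeric_predictors(newdata)))
    },
    label = "lm"
  )
}

#' @rdname predictor_lm
#' @export
predictor_mean <- function() {
  list(
    fit = function(data, y) mean(y),
    predict = function(model, newdata) rep(model, nrow(newdata)),
    label = "mean"
  )
}

#' @rdname predictor_lm
#' @param ... Passed to [randomForest::randomForest()].
#' @export
predictor_rf <- function(...) {
  if (!requireNamespace("randomForest", quietly = TRUE)) {
    abort("predictor_rf requires the randomForest package",
      class = "darktaxa_validation_error"
    )
  }
  args <- list(...)
  list(
    fit = function(data, y) {
      do.call(
        randomForest::randomForest,
        c(list(x = numeric_predictors(data), y = y), args)
      )
    },
    predict = function(model, newdata) {
      unname(stats::predict(model, newdata = numeric_predictors(newdata)))
    },
    label = "randomForest"
  )
}

numeric_predictors <- function(data) {
  df <- as.data.frame(data)[, vapply(data, is.numeric, logical(1)),
    drop = FALSE
  ]
  df
}

#' Niche histograms for a group against the null
#'
#' Weighted occurrence counts for a group and unweighted site counts for
#' the null distribution over shared bin edges. The group histogram sums
#' to the group's total weight; the null histogram sums to the number of
#' non-missing sites.
#'
#' @inheritParams group_env_sample
#' @param bins Number of equal-width bins over the null range (>= 2), or
#'   a numeric vector of explicit bin edges.
#' @return A tibble of class `niche_histogram` with `bin_left`,
#'   `bin_right`, `group_weight`, `null_count`.
#' @export
niche_histogram <- function(occurrence, sites, members, variable,
                            bins = 10) {
  null_v <- null_env_sample(sites, variable)
  grp <- group_env_sample(occurrence, sites, members, variable)
  if (length(bins) == 1L) {
    if (bins < 2) {
      abort("need at least 2 bins", class = "darktaxa_validation_error")
    }
    edges <- seq(min(null_v), max(null_v), length.out = bins + 1L)
  } else {
    edges <- sort(bins)
  }
  cut_idx <- function(x) {
    pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
      length(edges) - 1L
    )
  }
  gw <- tapply(grp$weight, base::factor(cut_idx(grp$value),
    levels = seq_len(length(edges) - 1L)
  ), sum)
  nc <- tabulate(cut_idx(null_v), nbins = length(edges) - 1L)
  out <- tibble(
    bin_left = edges[-length(edges)],
    bin_right = edges[-1L],
    group_weight = as.numeric(ifelse(is.na(gw), 0, gw)),
    null_count = nc
  )
  class(out) <- c("niche_histogram", class(out))
  attr(out, "variable") <- variable
  out
}

#' Write a niche report table
#'
#' @param niche A `niche_result` tibble from [niche_narrowness()].
#' @param bias Optional output of [categorical_bias_test()] to join
#'   (columns `bias_factor`, `bias_p` appended).
#' @param path Output TSV path.
#' @return The written tibble, invisibly.
#' @export
write_niche_report <- function(niche, path, bias = NULL) {
  out <- as_tibble(niche)
  if (!is.null(bias)) {
    out <- out |>
      left_join(
        bias |>
          select("group_id",
            bias_factor = "factor", bias_p = "p_value"
          ),
        by = "group_id"
      )
  }
  readr::write_tsv(out, path, na = "NA")
  invisible(out)
}
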