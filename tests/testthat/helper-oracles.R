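# Independent oracles and fixture builders used across the suite.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent point-substitution helper (deliberately distinct from the
# package's internal mutation machinery).
mutate_at <- function(seq, q) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < q)
  for (i in hit) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  }
  paste(v, collapse = "")
}

# Brute-force DP oracle: ends-free global alignment maximising matches
# (match 1, mismatch 0) with an infinitesimal gap cost. Returns the
# maximum match count.
dp_max_matches <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  eps <- 1e-4
  n <- length(va)
  m <- length(vb)
  h <- matrix(0, n + 1, m + 1) # free leading end gaps
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      h[i + 1, j + 1] <- max(
        h[i, j] + (va[i] == vb[j]),
        h[i, j + 1] - eps,
        h[i + 1, j] - eps
      )
    }
  }
  round(max(h[n + 1, ], h[, m + 1])) # free trailing end gaps
}

# Union-find connected components over an explicit link predicate.
brute_force_components <- function(ids, link) {
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (link(i, j)) {
        parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(ids, roots), sort))
}

# Canonical partition representation for comparing clusterings.
partition_of <- function(ids, labels) {
  p <- unname(lapply(split(ids, labels), sort))
  p[order(vapply(p, `[`, character(1), 1))]
}

# All permutations of a vector (exhaustive permutation-test oracle).
all_perms <- function(v) {
  if (length(v) <= 1L) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], p)
    }
  }
  out
}

# Independent G statistic (observed vs expected category weights).
g_stat_oracle <- function(w, f, share) {
  obs <- tapply(w, f, sum)
  obs[is.na(obs)] <- 0
  expected <- sum(w) * share
  keep <- obs > 0
  2 * sum(obs[keep] * log(obs[keep] / expected[keep]))
}

# Small two-clade OTU family for identity/clustering tests: `div_between`
# and `div_within` are per-pair target divergences.
toy_family <- function(n_per_clade = 4, len = 120, div_between = 0.3,
                       div_within = 0.03) {
  root <- rand_dna(len)
  anc <- list(mutate_at(root, div_between / 2), mutate_at(root, div_between / 2))
  tibble::tibble(
    otu_id = sprintf("T%02d", seq_len(2 * n_per_clade)),
    clade_id = rep(c("A", "B"), each = n_per_clade),
    sequence = unlist(lapply(anc, function(a) {
      vapply(seq_len(n_per_clade), function(i) mutate_at(a, div_within / 2),
        character(1)
      )
    }))
  )
}
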