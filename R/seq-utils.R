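#' Reverse complement of IUPAC DNA strings
#'
#' Vectorised over `x`; handles all IUPAC ambiguity codes and is an
#' involution.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  check_dna(toupper(x), seq_along(x))
  comp <- chartr(
    "ACGTRYSWKMBDHVN",
    "TGCAYRSWMKVHDBN",
    toupper(x)
  )
  vapply(
    strsplit(comp, ""),
    function(v) paste(rev(v), collapse = ""),
    character(1)
  )
}

#' GC fraction of unambiguous DNA strings
#'
#' @param x Character vector of A/C/G/T strings (ambiguity codes are an
#'   error: degenerate candidates are excluded before primer metrics are
#'   computed).
#' @return Numeric vector of (G+C)/length fractions.
#' @export
gc_fraction <- function(x) {
  x <- toupper(x)
  if (any(grepl("[^ACGT]", x))) {
    abort(
      "gc_fraction requires unambiguous A/C/G/T sequences",
      class = "darktaxa_validation_error"
    )
  }
  gc <- nchar(gsub("[AT]", "", x))
  gc / nchar(x)
}

# Unified nearest-neighbour duplex parameters: dH in kcal/mol, dS in
# cal/(mol K), keyed by the top-strand dinucleotide (the complementary
# stack shares the value).
nn_dh <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
nn_ds <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)

#' Oligonucleotide melting temperature
#'
#' Two estimators are provided. `"wallace"` is the 2/4 rule,
#' `Tm = 2 (A+T) + 4 (G+C)`. `"nearest_neighbor"` (the default) uses the
#' unified nearest-neighbour duplex parameters with duplex initiation
#' terms, an entropic monovalent-salt correction
#' (`0.368 (N-1) ln[Na+]`), and the `CT/4` concentration term for
#' non-self-complementary duplexes:
#' `Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15`.
#'
#' @param x Character vector of A/C/G/T primer sequences.
#' @param method `"nearest_neighbor"` or `"wallace"`.
#' @param oligo_uM Total oligonucleotide concentration in micromolar
#'   (nearest-neighbour only). Default 0.5.
#' @param na_mM Monovalent cation concentration in millimolar
#'   (nearest-neighbour only). Default 50.
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @export
melting_temperature <- function(x,
                                method = c("nearest_neighbor", "wallace"),
                                oligo_uM = 0.5,
                                na_mM = 50) {
  method <- match.arg(method)
  x <- toupper(x)
  if (any(grepl("[^ACGT]", x))) {
    abort(
      "melting_temperature requires unambiguous A/C/G/T sequences",
      class = "darktaxa_validation_error"
    )
  }
  if (method == "wallace") {
    at <- nchar(gsub("[GC]", "", x))
    gc <- nchar(x) - at
    return(2 * at + 4 * gc)
  }
  if (any(nchar(x) < 2)) {
    abort(
      "nearest-neighbor Tm requires length >= 2",
      class = "darktaxa_validation_error"
    )
  }
  r_gas <- 1.987 # cal / (mol K)
  ct <- oligo_uM * 1e-6
  na <- na_mM * 1e-3
  vapply(x, function(s) {
    n <- nchar(s)
    di <- substring(s, 1:(n - 1), 2:n)
    dh <- sum(nn_dh[di])
    ds <- sum(nn_ds[di])
    for (end in c(substr(s, 1, 1), substr(s, n, n))) {
      if (end %in% c("G", "C")) {
        dh <- dh + 0.1
        ds <- ds - 2.8
      } else {
        dh <- dh + 2.3
        ds <- ds + 4.1
      }
    }
    ds <- ds + 0.368 * (n - 1) * log(na)
    1000 * dh / (ds + r_gas * log(ct / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# Substitution-only mutation used throughout the simulator: each position
# is hit independently with probability `q` (scalar or per-position
# vector) and replaced by a uniform draw from the three alternative
# bases. `protect` is an optional logical mask of positions that never
# mutate (ultra-conserved priming sites).
mutate_sequence <- function(seq, q, protect = NULL) {
  if (all(q <= 0)) {
    return(seq)
  }
  v <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(v)) < q
  if (!is.null(protect)) {
    hit <- hit & !protect
  }
  idx <- which(hit)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    # vectorised draw of one of the three alternatives per hit site
    alt <- matrix(bases[t(vapply(v[idx], function(b) which(bases != b),
      integer(3)
    ))], ncol = 3)
    pick <- sample.int(3, length(idx), replace = TRUE)
    v[idx] <- alt[cbind(seq_along(idx), pick)]
  }
  paste(v, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-branch substitution probability for a branch of length `depth` under
# substitution rate `rate`: at least one Poisson event.
branch_q <- function(rate, depth) 1 - exp(-rate * depth)

# Rate giving an expected *pairwise* divergence D between two tips joined
# through a common ancestor at branch depth `depth` each, under the
# implemented scheme: D = 2q - (4/3) q^2 with q = 1 - exp(-rate*depth).
divergence_to_rate <- function(divergence, depth = 1) {
  a <- 4 / 3
  q <- (1 - sqrt(1 - a * divergence)) / a
  -log(1 - q) / depth
}
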