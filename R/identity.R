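id_submat <- NULL

identity_submat <- function() {
  # match = 1, mismatch = 0 (unit match scoring); built lazily once.
  if (is.null(id_submat)) {
    utils::assignInMyNamespace(
      "id_submat",
      Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = 0, baseOnly = FALSE
      )
    )
  }
  id_submat
}

align_overlap <- function(patterns, subject) {
  # Ends-free global alignment maximising the number of matches; an
  # infinitesimal gap cost picks the fewest-gap alignment among ties.
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(patterns),
    subject = Biostrings::DNAString(subject),
    type = "overlap",
    substitutionMatrix = identity_submat(),
    gapOpening = 0,
    gapExtension = 1e-4
  )
}

#' Pairwise sequence identity over the aligned overlap
#'
#' Identity between two sequences is defined from a global alignment with
#' free end gaps under unit match scoring (match 1, mismatch 0, near-zero
#' gap cost): `identity = matches / aligned columns` over the end-gap-free
#' span, and `overlap` is that span's column count. The measure is
#' symmetric in its arguments. Unrelated random DNA scores about 0.48
#' under this definition; sequences at 3% substitution divergence score
#' about 0.97.
#'
#' @param seq_a,seq_b DNA strings (non-empty).
#' @return A one-row tibble with `identity`, `overlap` and `matches`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    abort("pairwise_identity requires non-empty sequences",
      class = "darktaxa_validation_error"
    )
  }
  pair <- sort(c(toupper(seq_a), toupper(seq_b)))
  al <- align_overlap(pair[1], pair[2])
  cols <- Biostrings::nchar(al)
  m <- Biostrings::nmatch(al)
  tibble(identity = m / cols, overlap = cols, matches = m)
}

# All-vs-all identity and overlap matrices for a set of sequences,
# batching one subject against all later patterns per call.
identity_matrix <- function(seqs, ids = names(seqs)) {
  n <- length(seqs)
  ident <- matrix(1, n, n, dimnames = list(ids, ids))
  ov <- matrix(nchar(seqs), n, n, dimnames = list(ids, ids))
  if (n < 2) {
    return(list(identity = ident, overlap = ov))
  }
  for (i in seq_len(n - 1)) {
    al <- align_overlap(seqs[(i + 1):n], seqs[i])
    cols <- Biostrings::nchar(al)
    m <- Biostrings::nmatch(al)
    ident[i, (i + 1):n] <- m / cols
    ident[(i + 1):n, i] <- m / cols
    ov[i, (i + 1):n] <- cols
    ov[(i + 1):n, i] <- cols
  }
  list(identity = ident, overlap = ov)
}
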