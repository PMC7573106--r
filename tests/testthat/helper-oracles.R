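# Independent oracles used to cross-check the implementation.

# Brute-force binding-site scan: a window is a site iff SOME expanded
# concrete variant matches it with <= max_mismatches mismatches and none of
# that variant's mismatches falls in the protected 3' window. Equivalent to
# (but derived independently of) the IUPAC-set semantics.
oracle_binding_sites <- function(primer, target, policy, orientation) {
  v <- expand_primer(if (inherits(primer, "degenerate_primer")) primer
                     else degenerate_primer("p", primer))
  queries <- v$sequence
  offsets_fun <- function(L) (L - 1L):0L            # left-to-right, primer space
  if (orientation == "reverse") {
    queries <- vapply(queries, reverse_complement, "")
    # after reverse complementing, the primer's 3' terminus is the LEFT end
    offsets_fun <- function(L) 0L:(L - 1L)
  }
  L <- nchar(queries[1])
  n <- nchar(target)
  if (L > n) return(data.frame(start = integer(0), mismatch_count = integer(0)))
  tchars <- strsplit(target, "", fixed = TRUE)[[1]]
  W <- n - L + 1L
  wmat <- matrix(tchars[outer(seq_len(L) - 1L, seq_len(W), "+")], nrow = L)
  offs <- offsets_fun(L)
  starts <- integer(0)
  counts <- integer(0)
  for (w in seq_len(W)) {
    best <- NA_integer_
    for (q in queries) {
      qc <- strsplit(q, "", fixed = TRUE)[[1]]
      mis <- which(qc != wmat[, w])
      if (length(mis) <= policy$max_mismatches &&
          !any(offs[mis] < policy$protected_3prime)) {
        if (is.na(best) || length(mis) < best) best <- length(mis)
      }
    }
    if (!is.na(best)) {
      starts <- c(starts, w)
      counts <- c(counts, best)
    }
  }
  data.frame(start = starts, mismatch_count = counts)
}

# identity from the aligned strings of a global alignment, counting matched
# columns by character comparison (independent of Biostrings::nmatch)
oracle_global_identity <- function(a, b, type = "nucleotide") {
  if (type == "nucleotide") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 5, mismatch = -4, baseOnly = FALSE),
      gapOpening = 10, gapExtension = 4)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
  }
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(pa == sa & pa != "-") / length(pa)
}

# random IUPAC primer with a bounded number of ambiguity codes
random_primer <- function(len, n_ambig) {
  codes <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  pos <- sample(len, min(n_ambig, len))
  chars[pos] <- sample(codes, length(pos), replace = TRUE)
  paste(chars, collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
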