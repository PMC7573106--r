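# Read processing: trimming, dereplication, chimera detection, greedy
# identity clustering, read mapping.

#' Read amplicon reads from FASTA/FASTQ
#'
#' @param path File path (`.fastq`/`.fq` parsed as FASTQ, else FASTA; gzip
#'   allowed).
#' @param sample Sample label attached to every read (default: file stem).
#' @return Reads data.frame: `id`, `sequence`, `quality` (NA for FASTA),
#'   `sample`.
#' @export
read_amplicons <- function(path, sample = NULL) {
  if (is.null(sample)) sample <- sub("\\.(fastq|fq|fasta|fa|fna)(\\.gz)?$", "",
                                     basename(path))
  is_fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path)
  if (is_fastq) {
    set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(set)$qualities)
  } else {
    set <- Biostrings::readDNAStringSet(path)
    qual <- NA_character_
  }
  data.frame(id = sub("\\s.*$", "", names(set)),
             sequence = as.character(set), quality = qual, sample = sample,
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (constant quality if none recorded)
#'
#' @param reads Reads data.frame.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- ifelse(is.na(reads$quality),
                 vapply(nchar(reads$sequence),
                        function(n) strrep("I", n), ""),
                 reads$quality)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qual), con)
  invisible(path)
}

#' Trim and length/quality-filter reads
#'
#' Strips a configured 5' adaptor (exact prefix match) and, if a forward
#' primer is given, the primer footprint following it (the next
#' `nchar(primer)` bases, removed when they match the primer's IUPAC sets
#' with at most two mismatches). Optionally truncates at the first sliding
#' window whose mean quality falls below `min_qual`, then truncates to
#' `target_len` and discards shorter reads.
#'
#' @param reads Reads data.frame.
#' @param target_len Final read length (default 201).
#' @param adaptors Character vector of 5' adaptor sequences (optional).
#' @param primer Optional forward `degenerate_primer`/IUPAC string whose
#'   footprint follows the adaptor.
#' @param min_qual Optional mean-quality floor for sliding-window truncation.
#' @param window Sliding window width (default 4).
#' @return Filtered reads data.frame; attribute `log` records counts in/out.
#' @export
trim_and_filter <- function(reads, target_len = 201L, adaptors = NULL,
                            primer = NULL, min_qual = NULL, window = 4L) {
  n_in <- nrow(reads)
  seqs <- reads$sequence
  if (!is.null(adaptors)) {
    for (ad in adaptors) {
      hit <- startsWith(seqs, ad)
      seqs[hit] <- substring(seqs[hit], nchar(ad) + 1L)
      if (!is.null(reads$quality)) {
        qh <- hit & !is.na(reads$quality)
        reads$quality[qh] <- substring(reads$quality[qh], nchar(ad) + 1L)
      }
    }
  }
  if (!is.null(primer)) {
    pseq <- .primer_seq(primer)
    L <- nchar(pseq)
    pol <- match_policy(2L, 0L)
    hit <- vapply(seqs, function(s) {
      if (nchar(s) < L) return(FALSE)
      sites <- find_binding_sites(pseq, substr(s, 1L, L), pol, "forward")
      nrow(sites) > 0
    }, logical(1), USE.NAMES = FALSE)
    seqs[hit] <- substring(seqs[hit], L + 1L)
    if (!is.null(reads$quality)) {
      qh <- hit & !is.na(reads$quality)
      reads$quality[qh] <- substring(reads$quality[qh], L + 1L)
    }
  }
  if (!is.null(min_qual) && !all(is.na(reads$quality))) {
    for (i in which(!is.na(reads$quality))) {
      q <- utf8ToInt(reads$quality[i]) - 33L
      if (length(q) >= window) {
        means <- vapply(seq_len(length(q) - window + 1L),
                        function(s) mean(q[s:(s + window - 1L)]), numeric(1))
        bad <- which(means < min_qual)
        if (length(bad)) {
          cut <- bad[1] - 1L
          seqs[i] <- substr(seqs[i], 1L, cut)
          reads$quality[i] <- substr(reads$quality[i], 1L, cut)
        }
      }
    }
  }
  keep <- nchar(seqs) >= target_len
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substr(seqs[keep], 1L, target_len)
  if (!is.null(out$quality))
    out$quality <- ifelse(is.na(out$quality), NA,
                          substr(out$quality, 1L, target_len))
  rownames(out) <- NULL
  attr(out, "log") <- c(n_in = n_in, n_out = nrow(out))
  out
}

#' Dereplicate reads into unique sequences
#'
#' Exact-sequence grouping with abundances; groups below `min_abundance`
#' (singletons, by default) are dropped. Output order is deterministic:
#' abundance descending, then sequence ascending.
#'
#' @param reads Reads data.frame (equal-length sequences expected).
#' @param min_abundance Minimum group size retained (default 2).
#' @return data.frame `sequence`, `abundance`, `members` (list of read ids);
#'   attribute `log` has retained/dropped abundance totals.
#' @export
dereplicate <- function(reads, min_abundance = 2L) {
  groups <- split(reads$id, reads$sequence)
  ab <- lengths(groups)
  ord <- order(-ab, names(groups), method = "radix")
  groups <- groups[ord]
  ab <- ab[ord]
  keep <- ab >= min_abundance
  out <- data.frame(sequence = names(groups)[keep],
                    abundance = as.integer(ab[keep]),
                    stringsAsFactors = FALSE)
  out$members <- unname(groups[keep])
  attr(out, "log") <- c(n_reads = nrow(reads),
                        retained = sum(ab[keep]), dropped = sum(ab[!keep]))
  rownames(out) <- NULL
  out
}

# identity between two equal-length strings (no alignment)
.hamming_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(ca == cb)
}

#' Detect two-parent chimeras
#'
#' Simplified single-crossover model: a query is flagged iff some
#' concatenation of a parent prefix and another parent's suffix attains
#' identity to the query at least `min_divergence` above the best single
#' parent, and that model identity is at least `model_min`. In `denovo`
#' mode only uniques at least `skew`-fold more abundant than the query are
#' eligible parents. Sequences must share one length (the pipeline trims to
#' a fixed length upstream).
#'
#' @param uniques Dereplicated data.frame (`sequence`, `abundance`).
#' @param parents Reference parent sequences (character vector) for
#'   `reference` mode; ignored in `denovo` mode.
#' @param mode `"denovo"` or `"reference"`.
#' @param min_divergence Required identity gain of the two-parent model over
#'   the best single parent (default 0.02).
#' @param model_min Minimum two-parent model identity (default 0.98).
#' @param skew Abundance skew for de novo parent eligibility (default 2).
#' @param max_parents Cap on candidate parents per query, taken by
#'   decreasing abundance (default 20).
#' @return data.frame `sequence`, `is_chimera`, `best_single_identity`,
#'   `best_model_identity`.
#' @export
detect_chimeras <- function(uniques, parents = NULL,
                            mode = c("denovo", "reference"),
                            min_divergence = 0.02, model_min = 0.98,
                            skew = 2, max_parents = 20L) {
  mode <- match.arg(mode)
  if (mode == "reference" && (is.null(parents) || length(parents) == 0))
    stop("reference mode requires non-empty parents")
  seqs <- uniques$sequence
  n <- length(seqs)
  res <- data.frame(sequence = seqs, is_chimera = FALSE,
                    best_single_identity = NA_real_,
                    best_model_identity = NA_real_, stringsAsFactors = FALSE)
  if (n == 0) return(res)
  L <- nchar(seqs[1])
  qmat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  for (qi in seq_len(n)) {
    if (mode == "reference") {
      cand <- parents
    } else {
      elig <- which(uniques$abundance >= skew * uniques$abundance[qi] &
                      seq_len(n) != qi)
      cand <- seqs[elig[order(-uniques$abundance[elig])]]
    }
    cand <- unique(cand)
    cand <- cand[nchar(cand) == L]
    if (length(cand) > max_parents) cand <- cand[seq_len(max_parents)]
    if (length(cand) < 2) {
      if (length(cand) == 1)
        res$best_single_identity[qi] <- .hamming_identity(seqs[qi], cand)
      next
    }
    q <- qmat[qi, ]
    pmat <- do.call(rbind, strsplit(cand, "", fixed = TRUE))
    eq <- sweep(pmat, 2, q, "==") == TRUE   # parents x positions
    singles <- rowMeans(eq)
    h1 <- max(singles)
    # best single-crossover model: prefix matches of A + suffix matches of B
    pref <- t(apply(eq, 1, cumsum))                  # matches in 1..x
    tot <- pref[, L]
    best2 <- 0
    for (a in seq_len(nrow(eq))) {
      # suffix matches of every b beyond crossover x: tot_b - pref_b[x]
      suff_best <- apply(sweep(-pref, 1, tot, "+"), 2, max)  # max_b over x
      m <- max(c(pref[a, -L] + suff_best[-L], 0))
      best2 <- max(best2, m / L)
    }
    res$best_single_identity[qi] <- h1
    res$best_model_identity[qi] <- best2
    res$is_chimera[qi] <- (best2 >= h1 + min_divergence) && (best2 >= model_min)
  }
  res
}

# global pairwise identity: matches / alignment columns (end gaps penalized)
.global_identity <- function(patterns, subject, type = c("nucleotide", "peptide")) {
  type <- match.arg(type)
  if (type == "nucleotide") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 5, mismatch = -4, baseOnly = FALSE),
      gapOpening = 10, gapExtension = 4)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1)
  }
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Translate a nucleotide sequence in frame 0 (no start/stop rules)
#'
#' Stops translate to `*`; trailing partial codons are dropped. Used for
#' peptide-space clustering; start/stop filtering lives in
#' [translate_filter()].
#'
#' @param seq Nucleotide string.
#' @param table Genetic code table id (default 11).
#' @return Peptide string.
#' @export
translate_frame0 <- function(seq, table = 11L) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  code <- Biostrings::getGeneticCode(as.character(table))
  codons <- substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- code[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Greedy centroid clustering of unique sequences
#'
#' Processes uniques in (abundance desc, length desc, sequence asc) order;
#' each sequence joins the first existing centroid with global-alignment
#' identity >= `identity` (identity = matches / alignment columns, end gaps
#' penalized), else founds a new centroid. `on = "peptide"` clusters the
#' frame-0 translations.
#'
#' @param uniques Dereplicated data.frame.
#' @param identity Identity cutoff (default 0.90).
#' @param on `"nucleotide"` or `"peptide"`.
#' @param table Genetic code table for peptide space.
#' @return data.frame of OTUs: `otu`, `centroid` (nucleotide sequence),
#'   `abundance` (summed member abundance), `members` (list of member
#'   sequences).
#' @export
cluster_greedy <- function(uniques, identity = 0.90,
                           on = c("nucleotide", "peptide"), table = 11L) {
  on <- match.arg(on)
  if (nrow(uniques) == 0)
    return(data.frame(otu = character(0), centroid = character(0),
                      abundance = integer(0)))
  ord <- order(-uniques$abundance, -nchar(uniques$sequence), uniques$sequence,
               method = "radix")
  u <- uniques[ord, , drop = FALSE]
  space <- if (on == "peptide")
    vapply(u$sequence, translate_frame0, "", table = table, USE.NAMES = FALSE)
  else u$sequence
  cent_idx <- integer(0)
  assign <- integer(nrow(u))
  for (i in seq_len(nrow(u))) {
    joined <- FALSE
    if (length(cent_idx)) {
      ids <- .global_identity(space[cent_idx], space[i],
                              if (on == "peptide") "peptide" else "nucleotide")
      hit <- which(ids >= identity)
      if (length(hit)) {
        assign[i] <- hit[1]
        joined <- TRUE
      }
    }
    if (!joined) {
      cent_idx <- c(cent_idx, i)
      assign[i] <- length(cent_idx)
    }
  }
  otus <- data.frame(
    otu = sprintf("OTU_%03d", seq_along(cent_idx)),
    centroid = u$sequence[cent_idx],
    abundance = as.integer(tapply(u$abundance, assign, sum)),
    stringsAsFactors = FALSE)
  otus$members <- unname(split(u$sequence, assign))
  otus
}

#' Map reads to OTU centroids
#'
#' Each read is assigned to the highest-identity centroid with identity at
#' least `identity` (ties broken by centroid order); per-sample counts are
#' accumulated and unassigned reads counted separately.
#'
#' @param reads Trimmed reads data.frame (`sequence`, `sample`).
#' @param otus OTU data.frame from [cluster_greedy()] (or any data.frame
#'   with `otu` and `centroid`).
#' @param identity Identity cutoff (default 0.90).
#' @return List: `table` (integer matrix OTU x sample), `unmapped` (per
#'   sample), `assignments` (per-read OTU or NA).
#' @export
map_reads <- function(reads, otus, identity = 0.90) {
  samples <- sort(unique(reads$sample))
  tab <- matrix(0L, nrow(otus), length(samples),
                dimnames = list(otus$otu, samples))
  unmapped <- stats::setNames(integer(length(samples)), samples)
  if (nrow(reads) == 0) return(list(table = tab, unmapped = unmapped,
                                    assignments = character(0)))
  uniq <- unique(reads$sequence)
  idmat <- vapply(seq_len(nrow(otus)), function(k)
    .global_identity(uniq, otus$centroid[k], "nucleotide"),
    numeric(length(uniq)))
  idmat <- matrix(idmat, nrow = length(uniq))
  best <- apply(idmat, 1, function(r) {
    ok <- which(r >= identity)
    if (length(ok)) ok[which.max(r[ok])] else NA_integer_
  })
  assign_u <- ifelse(is.na(best), NA_character_, otus$otu[best])
  assignments <- assign_u[match(reads$sequence, uniq)]
  for (s in samples) {
    a <- assignments[reads$sample == s]
    unmapped[s] <- sum(is.na(a))
    cnt <- table(factor(a[!is.na(a)], levels = otus$otu))
    tab[, s] <- as.integer(cnt)
  }
  list(table = tab, unmapped = unmapped, assignments = assignments)
}

#' Run the amplicon pipeline end to end
#'
#' trim -> dereplicate -> (optional chimera filter) -> greedy clustering ->
#' read mapping. The chimera toggle and clustering space reproduce the four
#' common method variants (nucleotide/peptide clustering, with/without
#' chimera pre-filter).
#'
#' @param reads Raw reads data.frame.
#' @param target_len,adaptors,primer Passed to [trim_and_filter()].
#' @param min_abundance Passed to [dereplicate()].
#' @param chimera_filter Remove de novo chimeras before clustering?
#' @param identity Clustering/mapping identity cutoff.
#' @param on Clustering space (`"nucleotide"`/`"peptide"`).
#' @param chimera_args List of extra arguments for [detect_chimeras()].
#' @return List: `otu_table`, `otus`, `uniques`, `reads` (trimmed),
#'   `chimeras` (report or NULL), `log` (per-stage counts).
#' @export
run_pipeline <- function(reads, target_len = 201L, adaptors = NULL,
                         primer = NULL, min_abundance = 2L,
                         chimera_filter = TRUE, identity = 0.90,
                         on = "nucleotide", chimera_args = list()) {
  trimmed <- trim_and_filter(reads, target_len, adaptors, primer)
  uniques <- dereplicate(trimmed, min_abundance)
  chim <- NULL
  if (chimera_filter && nrow(uniques) > 0) {
    chim <- do.call(detect_chimeras,
                    c(list(uniques = uniques, mode = "denovo"), chimera_args))
    uniques <- uniques[!chim$is_chimera, , drop = FALSE]
  }
  otus <- cluster_greedy(uniques, identity, on)
  mapped <- map_reads(trimmed, otus, identity)
  list(otu_table = mapped$table, otus = otus, uniques = uniques,
       reads = trimmed, chimeras = chim,
       log = list(raw = nrow(reads), trimmed = nrow(trimmed),
                  uniques = nrow(uniques), otus = nrow(otus),
                  unmapped = mapped$unmapped))
}

#' Write an OTU table as TSV (rows = OTUs, columns = samples)
#'
#' @param otu_table Integer matrix.
#' @param path Output path.
#' @export
write_otu_table <- function(otu_table, path) {
  df <- data.frame(otu = rownames(otu_table), otu_table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
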