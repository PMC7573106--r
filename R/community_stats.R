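# Downstream community summaries: rank aggregation, rarefaction, sequencing
# error rate, weighted UniFrac, PCoA.

#' Aggregate classified OTU counts at a taxonomic rank
#'
#' Sums OTU counts by lineage truncated at `rank` and normalizes per sample;
#' OTUs that are unclassified (or classified shallower than `rank`) are
#' tracked under the `"unclassified"` category so mass is conserved.
#'
#' @param classifications data.frame from [classify_batch()] (queries must
#'   match `rownames(counts)`).
#' @param counts Integer matrix OTU x sample (e.g. the pipeline OTU table).
#' @param rank One of `domain`..`species`.
#' @return data.frame `sample`, `taxon`, `count`, `abundance` (per-sample
#'   relative abundance; sums to 1).
#' @export
aggregate_rank <- function(classifications, counts, rank) {
  if (!rank %in% .RANKS) stop("unknown rank: ", rank)
  depth <- match(rank, .RANKS)
  m <- match(rownames(counts), classifications$query)
  if (any(is.na(m))) stop("classifications missing for some OTUs")
  taxon <- vapply(m, function(i) {
    if (classifications$status[i] != "classified") return("unclassified")
    parts <- strsplit(classifications$lineage[i], ";", fixed = TRUE)[[1]]
    if (length(parts) < depth) return("unclassified")
    paste(parts[seq_len(depth)], collapse = ";")
  }, "")
  out <- do.call(rbind, lapply(colnames(counts), function(s) {
    tot <- tapply(counts[, s], taxon, sum)
    tot <- tot[tot > 0 | names(tot) != "unclassified"]
    data.frame(sample = s, taxon = names(tot), count = as.integer(tot),
               abundance = as.numeric(tot) / sum(tot),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rarefaction curve for one sample
#'
#' Analytic mode is the hypergeometric expectation of richness at each
#' depth, `E[S_d] = sum_i (1 - choose(N - n_i, d)/choose(N, d))` (computed
#' via [vegan::rarefy()]); resample mode averages seeded subsamples without
#' replacement.
#'
#' @param counts Integer vector of per-OTU counts for one sample.
#' @param depths Subsample depths (each <= `sum(counts)`).
#' @param mode `"analytic"` or `"resample"`.
#' @param reps Resampling replicates (default 100).
#' @param seed Seed for resample mode.
#' @return data.frame `depth`, `richness` (plus `se` in resample mode).
#' @export
rarefaction_curve <- function(counts, depths, mode = c("analytic", "resample"),
                              reps = 100L, seed = NULL) {
  mode <- match.arg(mode)
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths > N)) stop("depth exceeds total count")
  if (mode == "analytic") {
    rich <- vapply(depths, function(d)
      as.numeric(suppressWarnings(
        vegan::rarefy(matrix(counts, nrow = 1), sample = d))),
      numeric(1))
    data.frame(depth = depths, richness = rich)
  } else {
    if (!is.null(seed)) set.seed(seed)
    pool <- rep(seq_along(counts), counts)
    sims <- vapply(depths, function(d) {
      r <- replicate(reps, length(unique(sample(pool, d))))
      c(mean(r), stats::sd(r) / sqrt(reps))
    }, numeric(2))
    data.frame(depth = depths, richness = sims[1, ], se = sims[2, ])
  }
}

#' Sequencing error rate against mock-community references
#'
#' Each read is globally aligned to its best-identity reference; errors are
#' mismatches plus inserted plus deleted bases, and the overall percent is
#' `100 * total errors / total aligned read bases` (the mothur seq.error
#' statistic).
#'
#' @param reads Reads data.frame (or character vector of sequences).
#' @param references Character vector of expected template sequences.
#' @return List: `overall_percent`, `per_read` (data.frame `sequence`,
#'   `n`, `best_ref`, `mismatches`, `indels`, `aligned_bases`).
#' @export
seq_error_rate <- function(reads, references) {
  if (length(references) == 0) stop("references must be non-empty")
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  tab <- table(seqs)
  uniq <- names(tab)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                     baseOnly = FALSE)
  stats_per_ref <- lapply(references, function(ref) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(uniq), Biostrings::DNAString(ref),
      type = "global", substitutionMatrix = submat,
      gapOpening = 10, gapExtension = 4)
    data.frame(match = Biostrings::nmatch(aln),
               mismatch = Biostrings::nmismatch(aln),
               indel = Biostrings::nchar(aln) - Biostrings::nmatch(aln) -
                 Biostrings::nmismatch(aln))
  })
  pick <- vapply(seq_along(uniq), function(i) {
    ident <- vapply(stats_per_ref, function(s)
      s$match[i] / (s$match[i] + s$mismatch[i] + s$indel[i]), numeric(1))
    which.max(ident)
  }, integer(1))
  per <- data.frame(
    sequence = uniq, n = as.integer(tab),
    best_ref = pick,
    mismatches = vapply(seq_along(uniq), function(i)
      stats_per_ref[[pick[i]]]$mismatch[i], numeric(1)),
    indels = vapply(seq_along(uniq), function(i)
      stats_per_ref[[pick[i]]]$indel[i], numeric(1)),
    aligned_bases = nchar(uniq), stringsAsFactors = FALSE)
  total_err <- sum((per$mismatches + per$indels) * per$n)
  total_bases <- sum(per$aligned_bases * per$n)
  list(overall_percent = 100 * total_err / total_bases, per_read = per)
}

#' Weighted UniFrac distances
#'
#' For communities whose mass sits on the leaves of a rooted tree, the raw
#' distance between two samples is `sum_e b_e |A_e - B_e|`, where `A_e` is
#' the fraction of community A descending through edge `e`; the normalized
#' variant divides by `sum_e b_e (A_e + B_e)`.
#'
#' @param profiles Numeric matrix samples x leaves (rows sum to 1); column
#'   names must name tree leaves.
#' @param tree Rooted `phylo` with branch lengths.
#' @param normalized Use the normalized variant? (default TRUE).
#' @return Symmetric distance matrix (samples x samples).
#' @export
weighted_unifrac <- function(profiles, tree, normalized = TRUE) {
  missing <- setdiff(colnames(profiles), tree$tip.label)
  if (length(missing))
    stop("profile categories with no tree leaf: ",
         paste(missing, collapse = ", "))
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  # per-edge mass for each sample
  mass <- matrix(0, nrow(profiles), nrow(tree$edge),
                 dimnames = list(rownames(profiles), NULL))
  leaf_mass <- matrix(0, nrow(profiles), length(tree$tip.label),
                      dimnames = list(rownames(profiles), tree$tip.label))
  leaf_mass[, colnames(profiles)] <- profiles
  for (e in seq_len(nrow(tree$edge)))
    mass[, e] <- rowSums(leaf_mass[, tree$tip.label[desc[[e]]], drop = FALSE])
  b <- tree$edge.length
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    raw <- sum(b * abs(mass[i, ] - mass[j, ]))
    if (normalized) {
      den <- sum(b * (mass[i, ] + mass[j, ]))
      raw <- if (den > 0) raw / den else 0
    }
    d[i, j] <- d[j, i] <- raw
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centering plus eigendecomposition of a symmetric distance matrix.
#' Axes are ordered by eigenvalue; axes with non-positive eigenvalues are
#' reported but excluded from the coordinates (no correction is applied).
#'
#' @param d Symmetric non-negative distance matrix.
#' @return List: `coordinates` (samples x positive axes), `eigenvalues`
#'   (all, including negatives), `percent_variance` (over positive
#'   eigenvalues).
#' @export
pcoa_ordination <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  sc <- stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE)
  eig <- sc$eig
  pos <- which(eig > 1e-12)
  coords <- sc$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  list(coordinates = coords, eigenvalues = eig,
       percent_variance = 100 * eig[pos] / sum(eig[pos]))
}
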