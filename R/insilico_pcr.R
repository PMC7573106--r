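# Mismatch-constrained in-silico PCR and primer audit statistics.

# round half away from zero at `digits` decimals, matching printed statistics
# (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Mismatch policy for primer-template matching
#'
#' @param max_mismatches Maximum allowed mismatches per binding site
#'   (default 2).
#' @param protected_3prime Number of primer bases at the 3' end, inclusive of
#'   the terminal base, within which no mismatch is tolerated (default 5;
#'   offsets 0..4 from the 3' terminus are protected).
#' @param n_policy How a target `N` scores: `"mismatch"` (default; an `N`
#'   matches only a primer `N`) or `"wildcard"` (an `N` matches anything).
#' @return A list with class `match_policy`.
#' @export
match_policy <- function(max_mismatches = 2L, protected_3prime = 5L,
                         n_policy = c("mismatch", "wildcard")) {
  stopifnot(max_mismatches >= 0, protected_3prime >= 0)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 protected_3prime = as.integer(protected_3prime),
                 n_policy = match.arg(n_policy)),
            class = "match_policy")
}

# logical match matrix: rows = target chars ACGTN, cols = primer positions
.allowed_matrix <- function(primer_chars, n_policy) {
  sets <- iupac_sets()[primer_chars]
  m <- vapply(sets, function(s) c(A = "A" %in% s, C = "C" %in% s,
                                  G = "G" %in% s, T = "T" %in% s,
                                  N = FALSE),
              logical(5))
  if (n_policy == "wildcard") m["N", ] <- TRUE else m["N", ] <- lengths(sets) == 4L
  m
}

.check_target_seq <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("target sequence contains non-ACGTN characters")
  seq
}

# scan one concrete-orientation query (primer space) along a target string;
# returns starts, mismatch counts and offsets (distances from the primer 3'
# end, position L has offset 0)
.scan_primer <- function(primer_chars, target, policy) {
  L <- length(primer_chars)
  n <- nchar(target)
  if (L > n) return(list(start = integer(0)))
  allowed <- .allowed_matrix(primer_chars, policy$n_policy)
  tchars <- strsplit(target, "", fixed = TRUE)[[1]]
  tidx <- match(tchars, c("A", "C", "G", "T", "N"))
  W <- n - L + 1L
  # rows = primer positions, cols = windows
  posmat <- outer(seq_len(L) - 1L, seq_len(W), "+")
  mism <- matrix(!allowed[cbind(tidx[posmat], rep(seq_len(L), W))], nrow = L)
  counts <- colSums(mism)
  offsets_by_pos <- L - seq_len(L)                 # offset from 3' end per row
  protected <- offsets_by_pos < policy$protected_3prime
  viol <- colSums(mism[protected, , drop = FALSE]) > 0
  keep <- which(counts <= policy$max_mismatches & !viol)
  list(start = keep,
       mismatch_count = counts[keep],
       offsets = lapply(keep, function(w) offsets_by_pos[which(mism[, w])]),
       window_chars = lapply(keep, function(w) tchars[w:(w + L - 1L)]))
}

# deterministic variant index for the window's best-matching concrete variant:
# at matching positions take the target base, at mismatches the set's first
# base; index in A<C<G<T rightmost-fastest order
.variant_id_for <- function(primer_chars, window_chars, name) {
  sets <- iupac_sets()[primer_chars]
  chosen <- mapply(function(s, b) if (b %in% s) b else s[1], sets, window_chars)
  sizes <- lengths(sets)
  ranks <- mapply(function(s, b) match(b, s) - 1L, sets, chosen)
  mult <- rev(cumprod(rev(c(sizes[-1], 1))))
  idx <- sum(ranks * mult) + 1L
  width <- max(2L, nchar(as.character(prod(sizes))))
  sprintf("%s-%0*d", name, width, idx)
}

#' Locate primer binding sites on a target sequence
#'
#' A primer position matches a target base iff the base is in the position's
#' IUPAC set, so degenerate positions never create mismatches against
#' concrete bases (equivalently: mismatches are counted against the best
#' concrete variant). A window is a binding site iff its mismatch count is
#' `<= max_mismatches` and no mismatch lies within `protected_3prime` bases
#' of the primer's 3' end. For `orientation = "reverse"` the primer is
#' matched as its reverse complement against the sense strand; the 3'
#' protection then applies at the left end of the footprint.
#'
#' Coordinates are 1-based inclusive on the target's sense strand.
#'
#' @param primer `degenerate_primer` or IUPAC string.
#' @param target A target sequence: a character scalar, or a list/one-row
#'   data.frame with fields `id` and `sequence`.
#' @param policy A [match_policy()].
#' @param orientation `"forward"` or `"reverse"`.
#' @return data.frame with columns `target_id`, `strand`, `start`, `end`,
#'   `mismatch_count`, `mismatch_offsets` (comma-joined distances from the
#'   primer 3' end; 0 = terminal base), `best_variant_id`; sorted by `start`.
#' @export
find_binding_sites <- function(primer, target, policy = match_policy(),
                               orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  pseq <- .primer_seq(primer)
  name <- .primer_name(primer)
  if (is.list(target)) {
    target_id <- target$id
    tseq <- target$sequence
  } else {
    target_id <- "target"
    tseq <- target
  }
  tseq <- .check_target_seq(tseq)
  L <- nchar(pseq)
  n <- nchar(tseq)
  primer_chars <- strsplit(pseq, "", fixed = TRUE)[[1]]
  scan_target <- if (orientation == "forward") tseq else
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", tseq), "", fixed = TRUE)[[1]]),
          collapse = "")
  hits <- .scan_primer(primer_chars, scan_target, policy)
  k <- length(hits$start)
  if (k == 0L) {
    return(data.frame(target_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      mismatch_count = integer(0),
                      mismatch_offsets = character(0),
                      best_variant_id = character(0), stringsAsFactors = FALSE))
  }
  if (orientation == "forward") {
    start <- hits$start
    strand <- "+"
  } else {
    # window [s, s+L-1] on the reverse-complemented target maps back to
    # [n - (s+L-1) + 1, n - s + 1] on the sense strand
    start <- n - (hits$start + L - 1L) + 1L
    strand <- "-"
  }
  out <- data.frame(
    target_id = target_id, strand = strand,
    start = start, end = start + L - 1L,
    mismatch_count = as.integer(hits$mismatch_count),
    mismatch_offsets = vapply(hits$offsets, function(o)
      paste(sort(o), collapse = ","), ""),
    best_variant_id = vapply(seq_len(k), function(i)
      .variant_id_for(primer_chars, hits$window_chars[[i]], name), ""),
    stringsAsFactors = FALSE
  )
  out[order(out$start), , drop = FALSE]
}

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Assemble a target sequence library
#'
#' @param ids Character vector of unique record ids.
#' @param sequences Nucleotide strings (A/C/G/T/N).
#' @param role One of `reference_gene`, `paralog`, `clone`, `amplicon`.
#' @param taxonomy Optional data.frame with column `id` plus any of the seven
#'   ranks `domain`..`species` (missing ranks become empty strings).
#' @return data.frame with columns `id`, `sequence`, `role`, and the seven
#'   rank columns.
#' @export
target_library <- function(ids, sequences,
                           role = c("reference_gene", "paralog", "clone", "amplicon"),
                           taxonomy = NULL) {
  role <- match.arg(role)
  if (anyDuplicated(ids)) stop("library ids must be unique")
  sequences <- vapply(sequences, .check_target_seq, "", USE.NAMES = FALSE)
  if (any(!nzchar(sequences))) stop("library sequences must be non-empty")
  lib <- data.frame(id = as.character(ids), sequence = sequences, role = role,
                    stringsAsFactors = FALSE)
  for (r in .RANKS) lib[[r]] <- ""
  if (!is.null(taxonomy)) {
    m <- match(lib$id, taxonomy$id)
    for (r in intersect(.RANKS, names(taxonomy)))
      lib[[r]] <- ifelse(is.na(m), "", as.character(taxonomy[[r]][m]))
    lib[is.na(lib)] <- ""
  }
  lib
}

#' Read a library from FASTA plus an optional taxonomy CSV
#'
#' The CSV must have a column `id` and may carry the seven rank columns
#' `domain`..`species`.
#'
#' @param fasta Path to a FASTA file.
#' @param taxonomy_csv Optional path to the taxonomy CSV.
#' @param role Record role, as in [target_library()].
#' @return Library data.frame.
#' @export
read_library <- function(fasta, taxonomy_csv = NULL, role = "reference_gene") {
  set <- Biostrings::readDNAStringSet(fasta)
  tax <- if (!is.null(taxonomy_csv))
    utils::read.csv(taxonomy_csv, stringsAsFactors = FALSE, colClasses = "character")
  target_library(sub("\\s.*$", "", names(set)), as.character(set),
                 role = role, taxonomy = tax)
}

.any_site <- function(primer, seq, policy, orientation) {
  if (orientation == "both") {
    nrow(find_binding_sites(primer, seq, policy, "forward")) > 0 ||
      nrow(find_binding_sites(primer, seq, policy, "reverse")) > 0
  } else {
    nrow(find_binding_sites(primer, seq, policy, orientation)) > 0
  }
}

#' Primer binding efficiency over a reference library
#'
#' Efficiency is the fraction of reference records carrying at least one
#' binding site under the policy, with a per-clade breakdown at a chosen
#' rank.
#'
#' @inheritParams find_binding_sites
#' @param library Library data.frame (role `reference_gene`).
#' @param rank Rank for the per-clade breakdown (default `"phylum"`).
#' @param orientation `"forward"`, `"reverse"` or `"both"` (default: search
#'   both strands).
#' @return List with `efficiency` (fraction), `n`, `hit_ids`, and
#'   `per_clade` (data.frame `clade`, `n`, `hits`, `fraction`).
#' @export
primer_efficiency <- function(primer, library, policy = match_policy(),
                              rank = "phylum", orientation = "both") {
  if (nrow(library) == 0) stop("library must be non-empty")
  hit <- vapply(library$sequence, .any_site, logical(1),
                primer = primer, policy = policy, orientation = orientation,
                USE.NAMES = FALSE)
  clade <- library[[rank]]
  per <- do.call(rbind, lapply(split(seq_along(clade), clade), function(i)
    data.frame(clade = clade[i[1]], n = length(i), hits = sum(hit[i]),
               fraction = mean(hit[i]), stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  list(efficiency = mean(hit), n = nrow(library), hit_ids = library$id[hit],
       per_clade = per)
}

#' Primer specificity screen against paralog decoys
#'
#' Counts paralog records carrying a binding site at each mismatch level
#' 0..`max_mismatches`; a level-`m` screen uses the policy's 3' protection
#' with `max_mismatches = m`, so exact hits nest inside mismatch-tolerant
#' hits.
#'
#' @inheritParams primer_efficiency
#' @param paralogs Library data.frame (role `paralog`).
#' @return data.frame with columns `max_mismatches`, `count`, `fraction`.
#' @export
specificity_screen <- function(primer, paralogs, policy = match_policy(),
                               orientation = "both") {
  if (nrow(paralogs) == 0) stop("paralog set must be non-empty")
  out <- lapply(0:policy$max_mismatches, function(m) {
    pol <- match_policy(m, policy$protected_3prime, policy$n_policy)
    hit <- vapply(paralogs$sequence, .any_site, logical(1),
                  primer = primer, policy = pol, orientation = orientation,
                  USE.NAMES = FALSE)
    data.frame(max_mismatches = m, count = sum(hit), fraction = mean(hit))
  })
  do.call(rbind, out)
}

# exact occurrence of each concrete variant across a set of sequences
# (searched on both strands); returns per-variant hit matrix [variant x seq]
.variant_hits <- function(primer, sequences) {
  v <- expand_primer(primer)
  subj <- Biostrings::DNAStringSet(sequences)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(v$sequence))
  fwd <- Biostrings::vcountPDict(pd, subj) > 0
  pd_rc <- Biostrings::PDict(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(v$sequence)))
  rev <- Biostrings::vcountPDict(pd_rc, subj) > 0
  list(variants = v, hits = fwd | rev)
}

#' Primer redundancy against a reference library
#'
#' The number (and percent, rounded to one decimal) of expanded variants
#' with zero exact binding sites anywhere in the library (either strand).
#'
#' @inheritParams primer_efficiency
#' @return List with `count`, `percent`, `degeneracy`, `unmatched_ids`,
#'   `matched_ids`.
#' @export
primer_redundancy <- function(primer, library) {
  if (nrow(library) == 0) stop("library must be non-empty")
  vh <- .variant_hits(primer, library$sequence)
  matched <- rowSums(vh$hits) > 0
  count <- sum(!matched)
  list(count = count,
       percent = round_half_up(100 * count / nrow(vh$variants), 1),
       degeneracy = nrow(vh$variants),
       unmatched_ids = vh$variants$id[!matched],
       matched_ids = vh$variants$id[matched])
}

#' Equal-distribution occurrence threshold
#'
#' The percent occurrence each variant would have if all variants amplified
#' equally: `100 / degeneracy`, rounded to two decimals.
#'
#' @param degeneracy Positive integer.
#' @return Percent.
#' @examples
#' equal_distribution_threshold(32)  # 3.13
#' equal_distribution_threshold(96)  # 1.04
#' @export
equal_distribution_threshold <- function(degeneracy) {
  if (!is.numeric(degeneracy) || degeneracy < 1) stop("degeneracy must be >= 1")
  round_half_up(100 / degeneracy, 2)
}

#' Per-variant occurrence tally over observed sequences
#'
#' For each concrete variant, the number of observed sequences (clones or
#' amplicons) whose primer footprint exactly equals that variant, searched
#' on both strands. A sequence matching several variants (at different
#' positions) is credited to the lowest-index variant. Percents are over
#' sequences with any detected footprint and flagged when below the
#' equal-distribution threshold.
#'
#' @inheritParams primer_efficiency
#' @param observed Library data.frame (roles `clone`/`amplicon`) or a
#'   character vector of sequences.
#' @return data.frame `id`, `sequence`, `count`, `percent`,
#'   `below_threshold`, with attributes `n_with_footprint` and `threshold`.
#' @export
occurrence_tally <- function(primer, observed) {
  seqs <- if (is.data.frame(observed)) observed$sequence else observed
  v <- expand_primer(primer)
  thr <- equal_distribution_threshold(nrow(v))
  if (length(seqs) == 0) {
    out <- data.frame(id = v$id, sequence = v$sequence, count = 0L,
                      percent = 0, below_threshold = TRUE,
                      stringsAsFactors = FALSE)
    attr(out, "n_with_footprint") <- 0L
    attr(out, "threshold") <- thr
    return(out)
  }
  vh <- .variant_hits(primer, seqs)
  # credit each sequence once, to its lowest-index matching variant
  first_hit <- apply(vh$hits, 2, function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_integer_
  })
  counts <- tabulate(first_hit[!is.na(first_hit)], nbins = nrow(v))
  n_fp <- sum(!is.na(first_hit))
  pct <- if (n_fp > 0) 100 * counts / n_fp else rep(0, nrow(v))
  out <- data.frame(id = v$id, sequence = v$sequence, count = counts,
                    percent = pct, below_threshold = pct < thr,
                    stringsAsFactors = FALSE)
  attr(out, "n_with_footprint") <- n_fp
  attr(out, "threshold") <- thr
  out
}

#' Per-column conservation profile of an aligned region
#'
#' For each column, the mean over all unordered sequence pairs of the
#' indicator that the two bases are equal, expressed as a percent, with the
#' three-way category used for conservation displays: `full` (100%),
#' `mid` (30 to <100%), `low` (<30%).
#'
#' @param aligned Character vector of equal-length sequences.
#' @return data.frame `position`, `mean_pairwise_identity` (percent, one
#'   decimal), `category`.
#' @export
conservation_profile <- function(aligned) {
  if (length(aligned) < 2) stop("need at least 2 sequences")
  if (length(unique(nchar(aligned))) != 1) stop("sequences must have equal lengths")
  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  n <- nrow(mat)
  npairs <- n * (n - 1) / 2
  mpi <- apply(mat, 2, function(col) {
    tab <- table(col)
    100 * sum(tab * (tab - 1) / 2) / npairs
  })
  category <- ifelse(mpi == 100, "full", ifelse(mpi >= 30, "mid", "low"))
  data.frame(position = seq_along(mpi),
             mean_pairwise_identity = round_half_up(mpi, 1),
             category = category, stringsAsFactors = FALSE)
}

#' Apply positional edits to a degenerate primer
#'
#' @inheritParams degeneracy
#' @param edits Named character vector or list: names are 1-based positions
#'   from the 5' end, values the new IUPAC codes.
#' @return The edited `degenerate_primer`, with attributes
#'   `degeneracy_before` and `degeneracy_after`.
#' @examples
#' p <- degenerate_primer("uni-R", "CABGCNCCRCAYTCCATRCA")
#' apply_edits(p, c("3" = "G", "9" = "G", "15" = "S"))
#' @export
apply_edits <- function(primer, edits) {
  seq <- .primer_seq(primer)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  before <- degeneracy(seq)
  if (length(edits)) {
    pos <- as.integer(names(edits))
    if (any(is.na(pos)) || any(pos < 1) || any(pos > length(chars)))
      stop("edit positions out of range")
    codes <- toupper(unlist(edits, use.names = FALSE))
    if (any(!codes %in% names(iupac_sets()))) stop("invalid IUPAC code in edits")
    chars[pos] <- codes
  }
  out <- degenerate_primer(.primer_name(primer), paste(chars, collapse = ""))
  attr(out, "degeneracy_before") <- before
  attr(out, "degeneracy_after") <- degeneracy(out)
  out
}

#' Data-driven degeneracy reduction
#'
#' Locates exact primer footprints across a reference library, tallies the
#' base frequency at every primer position among those footprints (in primer
#' space), and restricts each position's IUPAC set to the bases whose
#' frequency is at least `min_base_freq`. A position is never emptied: if no
#' base passes the floor it falls back to the modal base.
#'
#' @inheritParams primer_efficiency
#' @param min_base_freq Frequency floor in `[0, 1]`.
#' @return List: `primer` (reduced), `degeneracy_before`, `degeneracy_after`,
#'   `removed_variants` (ids of variants no longer encoded),
#'   `position_freqs` (per-position base frequency matrix).
#' @export
reduce_degeneracy <- function(primer, library, min_base_freq) {
  seq <- .primer_seq(primer)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  vh <- .variant_hits(primer, library$sequence)
  hit_any <- rowSums(vh$hits) > 0
  if (!any(hit_any)) stop("no exact primer footprints found in library")
  # footprints in primer space: count, per position, the bases used by
  # variants observed in the library (each observed variant counted once per
  # sequence it occurs in)
  weights <- rowSums(vh$hits)
  fp_mat <- do.call(rbind, strsplit(vh$variants$sequence[hit_any], "", fixed = TRUE))
  w <- weights[hit_any]
  freqs <- sapply(seq_len(L), function(j) {
    tab <- tapply(w, factor(fp_mat[, j], levels = c("A", "C", "G", "T")), sum)
    tab[is.na(tab)] <- 0
    tab / sum(tab)
  })
  rownames(freqs) <- c("A", "C", "G", "T")
  code_of <- function(bases) {
    key <- paste(sort(bases), collapse = "")
    codes <- vapply(iupac_sets(), function(s) paste(sort(s), collapse = ""), "")
    names(codes)[match(key, codes)]
  }
  new_chars <- vapply(seq_len(L), function(j) {
    set <- iupac_sets()[[chars[j]]]
    fr <- freqs[set, j]
    keep <- set[fr >= min_base_freq]
    if (length(keep) == 0) keep <- set[which.max(fr)]
    code_of(keep)
  }, "")
  reduced <- degenerate_primer(paste0(.primer_name(primer), "-reduced"),
                               paste(new_chars, collapse = ""))
  kept <- expand_primer(reduced)$sequence
  removed <- vh$variants$id[!vh$variants$sequence %in% kept]
  list(primer = reduced,
       degeneracy_before = degeneracy(seq),
       degeneracy_after = degeneracy(reduced),
       removed_variants = removed,
       position_freqs = freqs)
}

#' Select an equimolar variant subset
#'
#' Drops variants whose percent occurrence is below `floor` in every
#' provided occurrence table (references, clones, amplicons, ...), mirroring
#' the removal of consistently underrepresented oligos when preparing
#' equimolar primer mixtures.
#'
#' @inheritParams degeneracy
#' @param occurrence_tables List of data.frames with columns `id` and
#'   `percent`, each covering every variant of `primer`.
#' @param floor Percent floor.
#' @return List: `kept` (variant data.frame), `dropped_ids`, `n_kept`.
#' @export
select_equimolar_subset <- function(primer, occurrence_tables, floor) {
  v <- expand_primer(primer)
  below <- rep(TRUE, nrow(v))
  for (tab in occurrence_tables) {
    m <- match(v$id, tab$id)
    if (any(is.na(m))) stop("occurrence table does not cover all variants")
    below <- below & (tab$percent[m] < floor)
  }
  list(kept = v[!below, , drop = FALSE], dropped_ids = v$id[below],
       n_kept = sum(!below))
}

#' Predict PCR amplicons from a primer pair
#'
#' Pairs every forward binding site with every downstream reverse site (the
#' reverse primer matched in reverse orientation on the sense strand); the
#' product spans and includes both footprints and is filtered by
#' `size_range`.
#'
#' @param fwd_primer,rev_primer Primers (5'->3').
#' @inheritParams find_binding_sites
#' @param size_range Length-2 numeric, inclusive product size bounds.
#' @return data.frame `start`, `end`, `length`, `sequence`.
#' @export
predict_amplicons <- function(fwd_primer, rev_primer, target,
                              policy = match_policy(),
                              size_range = c(200, 2000)) {
  tseq <- if (is.list(target)) target$sequence else target
  tseq <- .check_target_seq(tseq)
  f <- find_binding_sites(fwd_primer, tseq, policy, "forward")
  r <- find_binding_sites(rev_primer, tseq, policy, "reverse")
  out <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                    sequence = character(0), stringsAsFactors = FALSE)
  if (nrow(f) == 0 || nrow(r) == 0) return(out)
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
    if (r$start[j] > f$start[i]) {
      len <- r$end[j] - f$start[i] + 1L
      if (len >= size_range[1] && len <= size_range[2]) {
        out <- rbind(out, data.frame(
          start = f$start[i], end = r$end[j], length = len,
          sequence = substr(tseq, f$start[i], r$end[j]),
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Full primer audit
#'
#' Convenience wrapper producing the audit statistics for one primer:
#' efficiency against the reference library, redundancy, per-variant
#' occurrence over observed sequences, and (optionally) a specificity screen
#' against paralogs.
#'
#' @inheritParams primer_efficiency
#' @param observed Optional observed clone/amplicon library for the
#'   occurrence tally.
#' @param paralogs Optional paralog library for the specificity screen.
#' @return List with elements `efficiency`, `redundancy`, `threshold`,
#'   `occurrence` (or NULL), `specificity` (or NULL).
#' @export
primer_audit <- function(primer, library, policy = match_policy(),
                         observed = NULL, paralogs = NULL) {
  list(
    efficiency = primer_efficiency(primer, library, policy),
    redundancy = primer_redundancy(primer, library),
    threshold = equal_distribution_threshold(degeneracy(primer)),
    occurrence = if (!is.null(observed)) occurrence_tally(primer, observed),
    specificity = if (!is.null(paralogs))
      specificity_screen(primer, paralogs, policy)
  )
}
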