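# Taxonomy-annotated reference packages: region-trimmed alignments, profile
# models, rooted trees, taxonomy tables.

#' Region specification on an anchor record
#'
#' A named gene region (e.g. the short "201" or long "654" cap-helix
#' regions) anchored to the ungapped coordinates of one reference record.
#' The label is a name, not a length check: the region's extent is defined
#' entirely by the anchor interval.
#'
#' @param label Region label, e.g. `"201"` or `"654"`.
#' @param anchor_id Id of the anchor record.
#' @param start,end 1-based inclusive nucleotide coordinates on the anchor's
#'   ungapped gene sequence.
#' @return List with class `region_spec`.
#' @export
region_spec <- function(label, anchor_id, start, end) {
  stopifnot(start >= 1, end >= start)
  structure(list(label = as.character(label), anchor_id = anchor_id,
                 start = as.integer(start), end = as.integer(end)),
            class = "region_spec")
}

#' Trim an alignment to an anchored region
#'
#' Keeps exactly the alignment columns holding the anchor's ungapped
#' positions `start..end` (columns where the anchor has a gap between those
#' positions are dropped); all rows are cut to those columns.
#'
#' @param alignment Named character vector of equal-length gapped sequences.
#' @param region A [region_spec()]. The anchor must be a row of `alignment`.
#' @return Named character vector (the trimmed alignment).
#' @export
trim_to_region <- function(alignment, region) {
  if (!region$anchor_id %in% names(alignment))
    stop(sprintf("anchor '%s' not present in alignment", region$anchor_id))
  if (length(unique(nchar(alignment))) != 1)
    stop("alignment rows must have equal lengths")
  anchor <- strsplit(alignment[[region$anchor_id]], "", fixed = TRUE)[[1]]
  ungapped_cols <- which(anchor != "-")
  if (region$end > length(ungapped_cols))
    stop(sprintf("region interval %d..%d exceeds anchor ungapped length %d",
                 region$start, region$end, length(ungapped_cols)))
  cols <- ungapped_cols[region$start:region$end]
  vapply(alignment, function(s)
    paste(strsplit(s, "", fixed = TRUE)[[1]][cols], collapse = ""), "")
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Build a position-specific profile model from a peptide alignment
#'
#' Columns with less than 50% gaps become match columns. Each match column
#' stores pseudocounted residue frequencies; scoring a query sums the
#' per-column log2 odds against the alignment-wide background composition,
#' and the E-value-like inclusion statistic is `L * 2^(-score)` (smaller is
#' better; training peptides score far below typical inclusion thresholds
#' such as 1e-7, shuffled peptides do not).
#'
#' @param peptide_alignment Named character vector of equal-length aligned
#'   peptides (gap `-`).
#' @param pseudocount Dirichlet pseudocount per residue (default 0.5).
#' @return Object of class `aa_profile`: `log_odds` (20 x L matrix),
#'   `background`, `match_cols`, `length`.
#' @export
build_profile <- function(peptide_alignment, pseudocount = 0.5) {
  if (length(peptide_alignment) < 2) stop("need >= 2 aligned peptides")
  if (length(unique(nchar(peptide_alignment))) != 1)
    stop("alignment rows must have equal lengths")
  mat <- do.call(rbind, strsplit(toupper(peptide_alignment), "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  match_cols <- which(gap_frac < 0.5)
  if (length(match_cols) == 0) stop("alignment has no match columns")
  res <- mat[, match_cols, drop = FALSE]
  bg_tab <- table(factor(res[res %in% .AA20], levels = .AA20))
  background <- (bg_tab + pseudocount) / sum(bg_tab + pseudocount)
  lo <- sapply(seq_along(match_cols), function(j) {
    col <- res[, j]
    tab <- table(factor(col[col %in% .AA20], levels = .AA20))
    p <- (tab + pseudocount * 20 * background) / (sum(tab) + pseudocount * 20)
    log2(as.numeric(p) / as.numeric(background))
  })
  rownames(lo) <- .AA20
  structure(list(log_odds = lo, background = as.numeric(background),
                 match_cols = match_cols, length = length(match_cols)),
            class = "aa_profile")
}

#' Score a peptide against a profile
#'
#' If the query length differs from the profile length, the best-scoring
#' ungapped offset of the shorter within the longer is used. Residues
#' outside the 20-letter alphabet contribute 0.
#'
#' @param profile An `aa_profile`.
#' @param peptide Peptide string (gaps ignored).
#' @return Score in bits.
#' @export
profile_score <- function(profile, peptide) {
  chars <- strsplit(gsub("-", "", toupper(peptide)), "", fixed = TRUE)[[1]]
  L <- profile$length
  n <- length(chars)
  ridx <- match(chars, .AA20)
  col_score <- function(qpos, cols) {
    ok <- !is.na(ridx[qpos])
    sum(profile$log_odds[cbind(ridx[qpos][ok], cols[ok])])
  }
  if (n == L) return(col_score(seq_len(n), seq_len(L)))
  if (n > L) {
    max(vapply(0:(n - L), function(off)
      col_score(seq_len(L) + off, seq_len(L)), numeric(1)))
  } else {
    max(vapply(0:(L - n), function(off)
      col_score(seq_len(n), seq_len(n) + off), numeric(1)))
  }
}

#' E-value-like inclusion statistic
#'
#' `inclusion = L * 2^(-score)`; compare against thresholds like 1e-7
#' (smaller means stronger profile membership).
#'
#' @inheritParams profile_score
#' @return Positive numeric.
#' @export
inclusion_value <- function(profile, peptide) {
  profile$length * 2^(-profile_score(profile, peptide))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper over [ape::nj()] so reference packages can be assembled
#' without an external tree-inference tool; externally computed
#' maximum-likelihood newick trees are the primary route ([load_tree()]).
#'
#' @param d A `dist` or symmetric matrix of peptide distances.
#' @return An unrooted `phylo` tree.
#' @export
build_nj_tree <- function(d) {
  ape::nj(stats::as.dist(d))
}

#' Load a newick tree for a reference package
#'
#' @param path Newick file with branch lengths.
#' @return `phylo` tree.
#' @export
load_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length)) stop("tree must carry branch lengths")
  tr
}

#' Root a tree on an outgroup (midpoint if none)
#'
#' @param tree `phylo`.
#' @param outgroup_ids Character vector of outgroup leaf labels (may be
#'   empty: midpoint rooting is then used).
#' @return Rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup_ids = character(0)) {
  if (length(outgroup_ids)) {
    missing <- setdiff(outgroup_ids, tree$tip.label)
    if (length(missing))
      stop("outgroup leaves not in tree: ", paste(missing, collapse = ", "))
    # fall back to a single-leaf root when the outgroup set is not
    # monophyletic in the unrooted tree
    tryCatch(ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE),
             error = function(e)
               ape::root(tree, outgroup = outgroup_ids[1], resolve.root = TRUE))
  } else {
    phangorn::midpoint(tree)
  }
}

#' Assemble a reference package
#'
#' Bundles the region-trimmed nucleotide and peptide alignments, profile
#' model, rooted tree, 7-rank taxonomy and outgroup flags used for
#' placement-based classification. Validates that leaves, alignment rows
#' and taxonomy rows coincide.
#'
#' @param name Package name.
#' @param region A [region_spec()].
#' @param nuc_alignment,pep_alignment Named character vectors (equal-length
#'   rows; names are record ids).
#' @param tree Rooted `phylo` with branch lengths; tip labels = record ids.
#' @param taxonomy data.frame with columns `id`, `domain`..`species`
#'   (missing ranks as empty strings).
#' @param outgroup_ids Leaf ids flagged as non-methylator paralog outgroup.
#' @param profile Optional prebuilt `aa_profile` (default: built from
#'   `pep_alignment`).
#' @param seed Optional integer recorded in the manifest.
#' @return Object of class `refpkg`.
#' @export
reference_package <- function(name, region, nuc_alignment, pep_alignment,
                              tree, taxonomy, outgroup_ids = character(0),
                              profile = NULL, seed = NULL) {
  pkg <- structure(list(
    manifest = list(name = name, region = unclass(region),
                    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    seed = seed, format_version = "1"),
    nuc_alignment = nuc_alignment,
    pep_alignment = pep_alignment,
    profile = if (is.null(profile)) build_profile(pep_alignment) else profile,
    tree = tree,
    taxonomy = taxonomy,
    outgroup_ids = outgroup_ids
  ), class = "refpkg")
  validate_refpkg(pkg)
  pkg
}

#' Validate a reference package
#'
#' Asserts leaf set == alignment ids == taxonomy ids, equal alignment row
#' lengths, outgroups in the leaf set, and a rooted tree.
#'
#' @param pkg A `refpkg`.
#' @return Invisibly `pkg`; errors name the offending ids.
#' @export
validate_refpkg <- function(pkg) {
  leaves <- sort(pkg$tree$tip.label)
  for (what in c("nuc_alignment", "pep_alignment")) {
    ids <- sort(names(pkg[[what]]))
    if (!identical(leaves, ids))
      stop(sprintf("%s ids differ from tree leaves: %s", what,
                   paste(union(setdiff(leaves, ids), setdiff(ids, leaves)),
                         collapse = ", ")))
    if (length(unique(nchar(pkg[[what]]))) != 1)
      stop(what, " rows have unequal lengths")
  }
  tax_ids <- sort(pkg$taxonomy$id)
  if (!identical(leaves, tax_ids))
    stop("taxonomy ids differ from tree leaves: ",
         paste(union(setdiff(leaves, tax_ids), setdiff(tax_ids, leaves)),
               collapse = ", "))
  if (!all(pkg$outgroup_ids %in% leaves))
    stop("outgroup ids not in tree: ",
         paste(setdiff(pkg$outgroup_ids, leaves), collapse = ", "))
  if (!ape::is.rooted(pkg$tree)) stop("tree must be rooted")
  invisible(pkg)
}

# pairwise identity of two equal-length aligned peptides:
# matches / alignment columns
.aln_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(ca == cb & ca != "-") / length(ca)
}

#' Collapse reference leaves by peptide identity
#'
#' Complete-linkage clusters the (non-outgroup) aligned reference peptides
#' at the identity cutoff, keeps one representative leaf per cluster (the
#' lexicographically smallest id) and drops the rest from the tree.
#'
#' @param pkg A `refpkg`.
#' @param cutoff Identity cutoff in (0, 1], e.g. 0.90 or 0.80.
#' @return List: `tree` (collapsed), `clusters` (data.frame `id`, `cluster`,
#'   `representative`), `n_before`, `n_after`.
#' @export
collapse_by_identity <- function(pkg, cutoff) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  ids <- setdiff(pkg$tree$tip.label, pkg$outgroup_ids)
  pep <- pkg$pep_alignment[ids]
  n <- length(pep)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - .aln_identity(pep[[i]], pep[[j]])
  }
  cl <- if (n > 1) {
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    stats::cutree(hc, h = 1 - cutoff + 1e-9)
  } else stats::setNames(1L, ids)
  reps <- vapply(split(ids, cl), function(members) sort(members)[1], "")
  keep <- c(unname(reps), pkg$outgroup_ids)
  tree <- ape::drop.tip(pkg$tree, setdiff(pkg$tree$tip.label, keep))
  list(tree = tree,
       clusters = data.frame(id = ids, cluster = unname(cl),
                             representative = unname(reps[as.character(cl)]),
                             stringsAsFactors = FALSE),
       n_before = length(ids) + length(pkg$outgroup_ids),
       n_after = length(keep))
}

.write_fasta <- function(x, path) {
  set <- Biostrings::BStringSet(unlist(x))
  Biostrings::writeXStringSet(set, path)
}

#' Save a reference package to a directory
#'
#' Layout: `manifest.json`, `nuc_alignment.fasta`, `pep_alignment.fasta`,
#' `tree.nwk`, `taxonomy.csv`, `profile.json` — all plain text.
#'
#' @param pkg A `refpkg`.
#' @param path Directory (created if absent).
#' @return Invisibly `path`.
#' @export
save_refpkg <- function(pkg, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- pkg$manifest
  manifest$outgroup_ids <- as.list(pkg$outgroup_ids)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .write_fasta(pkg$nuc_alignment, file.path(path, "nuc_alignment.fasta"))
  .write_fasta(pkg$pep_alignment, file.path(path, "pep_alignment.fasta"))
  ape::write.tree(pkg$tree, file.path(path, "tree.nwk"))
  utils::write.csv(pkg$taxonomy, file.path(path, "taxonomy.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(log_odds = pkg$profile$log_odds, background = pkg$profile$background,
         match_cols = pkg$profile$match_cols, length = pkg$profile$length),
    file.path(path, "profile.json"), digits = NA)
  invisible(path)
}

#' Load a reference package from a directory
#'
#' @param path Directory written by [save_refpkg()].
#' @return A validated `refpkg`.
#' @export
load_refpkg <- function(path) {
  need <- c("manifest.json", "nuc_alignment.fasta", "pep_alignment.fasta",
            "tree.nwk", "taxonomy.csv", "profile.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("reference package is missing: ", paste(missing, collapse = ", "))
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  read_aln <- function(f) {
    set <- Biostrings::readBStringSet(file.path(path, f))
    stats::setNames(as.character(set), names(set))
  }
  pj <- jsonlite::read_json(file.path(path, "profile.json"),
                            simplifyVector = TRUE)
  lo <- as.matrix(pj$log_odds)
  rownames(lo) <- .AA20
  profile <- structure(list(log_odds = lo, background = pj$background,
                            match_cols = pj$match_cols, length = pj$length),
                       class = "aa_profile")
  region <- do.call(region_spec, manifest$region[c("label", "anchor_id",
                                                   "start", "end")])
  pkg <- reference_package(
    name = manifest$name, region = region,
    nuc_alignment = read_aln("nuc_alignment.fasta"),
    pep_alignment = read_aln("pep_alignment.fasta"),
    tree = load_tree(file.path(path, "tree.nwk")),
    taxonomy = utils::read.csv(file.path(path, "taxonomy.csv"),
                               stringsAsFactors = FALSE,
                               colClasses = "character"),
    outgroup_ids = as.character(unlist(manifest$outgroup_ids)),
    profile = profile, seed = manifest$seed)
  pkg$manifest$created <- manifest$created
  pkg
}
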