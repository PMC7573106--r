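# Translation filtering, profile filtering, phylogenetic placement, and
# LCA taxonomy calls.

#' Classifier configuration
#'
#' @param translation_table Genetic code table id (default 11, bacterial).
#' @param start_codons Allowed initiator codons; the default is the table-11
#'   initiator set, translated as M.
#' @param inclusion_threshold Profile inclusion cutoff (default 1e-7).
#' @param posterior_cutoff Minimum accumulated placement weight for a
#'   taxonomy call (default 0.90).
#' @param max_branch_length Placements attached to an edge at least this
#'   long are discarded before classification (default 1.0).
#' @param score_band Placements within this many residue differences of the
#'   best placement are retained (default 3).
#' @param lambda Per-residue-difference weight decay used to turn placement
#'   scores into like-weight ratios (default 2).
#' @return List with class `classifier_config`.
#' @export
classifier_config <- function(translation_table = 11L,
                              start_codons = c("ATG", "GTG", "TTG"),
                              inclusion_threshold = 1e-7,
                              posterior_cutoff = 0.90,
                              max_branch_length = 1.0,
                              score_band = 3, lambda = 2) {
  stopifnot(posterior_cutoff > 0, posterior_cutoff <= 1,
            inclusion_threshold > 0)
  structure(list(translation_table = translation_table,
                 start_codons = toupper(start_codons),
                 inclusion_threshold = inclusion_threshold,
                 posterior_cutoff = posterior_cutoff,
                 max_branch_length = max_branch_length,
                 score_band = score_band, lambda = lambda),
            class = "classifier_config")
}

#' Translate with start-codon and stop-codon rules
#'
#' Frame 0 is assumed. The read is rejected unless its first codon is an
#' allowed start codon (translated as M) and rejected if any stop codon
#' occurs anywhere in frame; the trailing partial codon is dropped.
#'
#' @param seq Nucleotide string (length >= 3).
#' @param config A [classifier_config()].
#' @return List: `status` (`"ok"`, `"no_start"`, `"internal_stop"`,
#'   `"too_short"`), `peptide` (or NA).
#' @export
translate_filter <- function(seq, config = classifier_config()) {
  seq <- toupper(seq)
  if (nchar(seq) < 3L) return(list(status = "too_short", peptide = NA_character_))
  n <- nchar(seq) - nchar(seq) %% 3L
  codons <- substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  if (!codons[1] %in% config$start_codons)
    return(list(status = "no_start", peptide = NA_character_))
  code <- Biostrings::getGeneticCode(as.character(config$translation_table))
  aa <- code[codons]
  aa[is.na(aa)] <- "X"
  if (any(aa == "*"))
    return(list(status = "internal_stop", peptide = NA_character_))
  aa[1] <- "M"
  list(status = "ok", peptide = paste(aa, collapse = ""))
}

#' Profile-based homolog filter
#'
#' Keeps peptides whose [inclusion_value()] against the package profile is
#' below the threshold; removed ids are reported with their scores.
#'
#' @param peptides Named character vector of peptides.
#' @param profile An `aa_profile` (e.g. `pkg$profile`).
#' @param threshold Inclusion threshold (default 1e-7).
#' @return List: `kept` (named character vector), `scores` (data.frame `id`,
#'   `inclusion`, `kept`).
#' @export
profile_filter <- function(peptides, profile, threshold = 1e-7) {
  inc <- vapply(peptides, inclusion_value, numeric(1), profile = profile)
  keep <- inc < threshold
  list(kept = peptides[keep],
       scores = data.frame(id = names(peptides), inclusion = unname(inc),
                           kept = unname(keep), stringsAsFactors = FALSE))
}

# per-leaf residue differences between query and ungapped leaf peptides,
# via global alignment (robust to length mismatches)
.leaf_differences <- function(peptide, pkg) {
  leaves <- pkg$tree$tip.label
  refs <- gsub("-", "", pkg$pep_alignment[leaves])
  ident <- .global_identity(refs, peptide, "peptide")
  widths <- pmax(nchar(refs), nchar(peptide))
  stats::setNames(round((1 - ident) * widths), leaves)
}

# branch length of each leaf's pendant edge
.pendant_lengths <- function(tree) {
  tips <- seq_along(tree$tip.label)
  idx <- match(tips, tree$edge[, 2])
  stats::setNames(tree$edge.length[idx], tree$tip.label)
}

#' Place a query peptide on the reference tree
#'
#' Distance-based placement: the query is scored against every pendant edge
#' by the residue differences between the query and that leaf's reference
#' peptide. Placements within `score_band` differences of the best are
#' retained; like-weight ratios are `exp(-lambda * extra_differences)`
#' normalized over the retained set (an approximation of posterior-style
#' placement weights, documented as such).
#'
#' @param peptide Query peptide string.
#' @param pkg A `refpkg`.
#' @param config A [classifier_config()].
#' @param query_id Id recorded in the result (default "query").
#' @return data.frame `query`, `edge` (leaf id of the pendant edge),
#'   `like_weight_ratio`, `branch_length` (attachment edge length),
#'   `pendant_length` (residue differences / alignment length).
#' @export
place_query <- function(peptide, pkg, config = classifier_config(),
                        query_id = "query") {
  nd <- .leaf_differences(peptide, pkg)
  best <- min(nd)
  keep <- which(nd <= best + config$score_band)
  w <- exp(-config$lambda * (nd[keep] - best))
  w <- w / sum(w)
  pend <- .pendant_lengths(pkg$tree)[names(keep)]
  out <- data.frame(query = query_id, edge = names(keep),
                    like_weight_ratio = unname(w),
                    branch_length = unname(pend),
                    pendant_length = unname(nd[keep]) / pkg$profile$length,
                    stringsAsFactors = FALSE)
  out[order(-out$like_weight_ratio, out$edge), , drop = FALSE]
}

.lineage_of <- function(taxonomy, id) {
  row <- taxonomy[taxonomy$id == id, , drop = FALSE]
  vapply(.RANKS, function(r)
    if (r %in% names(row) && nrow(row)) as.character(row[[r]][1]) else "", "")
}

#' LCA taxonomy call from placements
#'
#' Placements attached to an edge of length >= `max_branch_length` are
#' dropped (if none remain the query is unclassified). Remaining
#' like-weight ratios are accumulated along each placement leaf's lineage;
#' the call is the deepest rank whose best lineage prefix accumulates at
#' least `posterior_cutoff` weight. Calls that land inside the outgroup
#' (paralog) lineage get status `paralog`.
#'
#' @param placements data.frame from [place_query()].
#' @param pkg A `refpkg` (taxonomy + outgroup flags).
#' @param config A [classifier_config()].
#' @return One-row data.frame: `query`, `status` (`classified`/
#'   `unclassified`/`paralog`), `rank`, `lineage` (semicolon-joined call),
#'   `confidence`.
#' @export
classify_lca <- function(placements, pkg, config = classifier_config()) {
  query <- if (nrow(placements)) placements$query[1] else "query"
  empty <- data.frame(query = query, status = "unclassified",
                      rank = NA_character_, lineage = NA_character_,
                      confidence = NA_real_, stringsAsFactors = FALSE)
  if (nrow(placements) == 0) return(empty)
  pl <- placements[placements$branch_length < config$max_branch_length, ,
                   drop = FALSE]
  if (nrow(pl) == 0) return(empty)
  pl$like_weight_ratio <- pl$like_weight_ratio / sum(pl$like_weight_ratio)
  lineages <- lapply(pl$edge, .lineage_of, taxonomy = pkg$taxonomy)
  call_rank <- NA_character_
  call_prefix <- NULL
  confidence <- NA_real_
  for (depth in seq_along(.RANKS)) {
    prefixes <- vapply(lineages, function(l) {
      if (any(!nzchar(l[seq_len(depth)]))) NA_character_
      else paste(l[seq_len(depth)], collapse = ";")
    }, "")
    ok <- !is.na(prefixes)
    if (!any(ok)) break
    acc <- tapply(pl$like_weight_ratio[ok], prefixes[ok], sum)
    top <- which.max(acc)
    if (acc[top] >= config$posterior_cutoff) {
      call_rank <- .RANKS[depth]
      call_prefix <- names(acc)[top]
      confidence <- as.numeric(acc[top])
    } else break
  }
  if (is.na(call_rank)) return(empty)
  # paralog when every leaf compatible with the called prefix is an outgroup
  depth <- match(call_rank, .RANKS)
  compat <- vapply(pkg$taxonomy$id, function(id) {
    l <- .lineage_of(pkg$taxonomy, id)
    paste(l[seq_len(depth)], collapse = ";") == call_prefix
  }, logical(1))
  status <- if (all(pkg$taxonomy$id[compat] %in% pkg$outgroup_ids))
    "paralog" else "classified"
  data.frame(query = query, status = status, rank = call_rank,
             lineage = call_prefix, confidence = confidence,
             stringsAsFactors = FALSE)
}

#' Classify nucleotide queries end to end
#'
#' Per query: [translate_filter()] -> [profile_filter()] -> [place_query()]
#' -> [classify_lca()]. Failures become statuses (`filtered_translation`,
#' `filtered_profile`), never batch errors. Duplicate sequences are
#' classified once.
#'
#' @param sequences Named character vector of nucleotide sequences (OTU
#'   centroids or reads).
#' @param pkg A `refpkg`.
#' @param config A [classifier_config()].
#' @return data.frame: `query`, `status`, `rank`, `lineage`, `confidence`.
#' @export
classify_batch <- function(sequences, pkg, config = classifier_config()) {
  if (length(sequences) == 0)
    return(data.frame(query = character(0), status = character(0),
                      rank = character(0), lineage = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("query_%04d", seq_along(sequences))
  uniq <- !duplicated(sequences)
  cache <- list()
  one <- function(seq) {
    tr <- translate_filter(seq, config)
    if (tr$status != "ok")
      return(data.frame(query = "", status = "filtered_translation",
                        rank = NA_character_, lineage = NA_character_,
                        confidence = NA_real_, stringsAsFactors = FALSE))
    if (inclusion_value(pkg$profile, tr$peptide) >= config$inclusion_threshold)
      return(data.frame(query = "", status = "filtered_profile",
                        rank = NA_character_, lineage = NA_character_,
                        confidence = NA_real_, stringsAsFactors = FALSE))
    classify_lca(place_query(tr$peptide, pkg, config), pkg, config)
  }
  for (s in sequences[uniq]) cache[[s]] <- one(s)
  rows <- lapply(seq_along(sequences), function(i) {
    row <- cache[[sequences[[i]]]]
    row$query <- names(sequences)[i]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export placements as jplace-compatible JSON
#'
#' @param placements data.frame of placements (possibly several queries).
#' @param pkg A `refpkg` (its tree is embedded).
#' @param path Output path.
#' @export
write_jplace <- function(placements, pkg, path) {
  tree_str <- ape::write.tree(pkg$tree)
  leaf_num <- stats::setNames(seq_along(pkg$tree$tip.label),
                              pkg$tree$tip.label)
  pls <- lapply(split(placements, placements$query), function(d) {
    list(p = lapply(seq_len(nrow(d)), function(i)
      list(leaf_num[[d$edge[i]]], d$like_weight_ratio[i],
           d$branch_length[i], d$pendant_length[i])),
      nm = list(list(d$query[1], 1)))
  })
  jsonlite::write_json(
    list(version = 3, tree = tree_str,
         fields = c("edge_num", "like_weight_ratio", "branch_length",
                    "pendant_length"),
         placements = unname(pls), metadata = list(invocation = "hgcamplicon")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
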