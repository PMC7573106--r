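test_that("translation enforces start-codon and stop-codon rules", {
  expect_equal(translate_filter("ATGGCTGGT")$peptide, "MAG")
  expect_equal(translate_filter("ATGTAAGGT")$status, "internal_stop")
  # GTG and TTG are table-11 initiators, translated as M
  expect_equal(translate_filter("GTGGCTGGT")$peptide, "MAG")
  expect_equal(translate_filter("TTGGCTGGT")$peptide, "MAG")
  expect_equal(translate_filter("CTGGCTGGT")$status, "no_start")
  expect_equal(translate_filter("AT")$status, "too_short")
  # trailing partial codon dropped
  expect_equal(translate_filter("ATGGCTGG")$peptide, "MA")
})

test_that("profile filter keeps homologs and removes shuffles", {
  pkg <- shared_refpkg()
  peps <- stats::setNames(unname(pkg$pep_alignment), names(pkg$pep_alignment))
  kept <- profile_filter(peps, pkg$profile)
  expect_equal(sort(names(kept$kept)), sort(names(peps)))   # all refs pass
  set.seed(8)
  shuf <- vapply(1:100, function(i)
    paste(sample(strsplit(peps[[i %% 10 + 1]], "")[[1]]), collapse = ""), "")
  names(shuf) <- sprintf("shuf%03d", 1:100)
  res <- profile_filter(shuf, pkg$profile)
  expect_lte(length(res$kept), 5)
  expect_true(all(names(res$kept) %in% names(shuf)))        # output subset
})

test_that("placement puts identical queries on their own pendant edge", {
  pkg <- shared_refpkg()
  leaf <- setdiff(pkg$tree$tip.label, pkg$outgroup_ids)[1]
  pl <- place_query(pkg$pep_alignment[[leaf]], pkg, query_id = "self")
  expect_equal(pl$edge[1], leaf)
  expect_gte(pl$like_weight_ratio[1], 0.99)
  expect_equal(sum(pl$like_weight_ratio), 1)
})

test_that("a query equidistant between sister leaves splits its weight", {
  pkg <- make_tiny_refpkg()
  # intermediate between A and B: take A's residue at pos 5, B's at pos 9
  q <- pkg$pep_alignment[["A"]]
  substr(q, 9, 9) <- substr(pkg$pep_alignment[["B"]], 9, 9)
  pl <- place_query(q, pkg)
  expect_setequal(pl$edge[1:2], c("A", "B"))
  expect_equal(pl$like_weight_ratio[1], pl$like_weight_ratio[2], tolerance = 1e-9)
  expect_equal(sum(pl$like_weight_ratio), 1)
})

test_that("LCA calls obey cutoff, branch-length rule and outgroup flagging", {
  pkg <- make_tiny_refpkg()
  cfg <- classifier_config()
  # single full-weight placement on a fully ranked leaf -> species call
  pl <- data.frame(query = "q", edge = "A", like_weight_ratio = 1,
                   branch_length = 0.05, pendant_length = 0)
  cl <- classify_lca(pl, pkg, cfg)
  expect_equal(cl$status, "classified")
  expect_equal(cl$rank, "species")
  expect_equal(cl$confidence, 1.0)
  expect_match(cl$lineage, "SpA$")
  # 0.5/0.5 across two genera of one family -> family-level call
  pl2 <- data.frame(query = "q", edge = c("A", "B"),
                    like_weight_ratio = c(0.5, 0.5),
                    branch_length = c(0.05, 0.05), pendant_length = 0)
  cl2 <- classify_lca(pl2, pkg, cfg)
  expect_equal(cl2$rank, "family")
  expect_match(cl2$lineage, "FamX$")
  expect_equal(cl2$confidence, 1.0)
  # sole placement with attachment branch length 1.2 -> unclassified
  pl3 <- data.frame(query = "q", edge = "D", like_weight_ratio = 1,
                    branch_length = 1.2, pendant_length = 0)
  expect_equal(classify_lca(pl3, pkg, cfg)$status, "unclassified")
  # outgroup placement -> paralog
  pl4 <- data.frame(query = "q", edge = "OG", like_weight_ratio = 1,
                    branch_length = 0.8, pendant_length = 0)
  expect_equal(classify_lca(pl4, pkg, cfg)$status, "paralog")
  # empty placements -> unclassified
  expect_equal(classify_lca(pl4[0, ], pkg, cfg)$status, "unclassified")
})

test_that("confidence is non-increasing with depth; cutoff and branch filters are monotone", {
  pkg <- make_tiny_refpkg()
  q <- pkg$pep_alignment[["A"]]
  substr(q, 9, 9) <- substr(pkg$pep_alignment[["B"]], 9, 9)
  pl <- place_query(q, pkg)
  # raising the cutoff never deepens the call
  ranks <- match(vapply(c(0.5, 0.9, 0.99), function(co) {
    cl <- classify_lca(pl, pkg, classifier_config(posterior_cutoff = co))
    if (is.na(cl$rank)) "none" else cl$rank
  }, ""), c(.RANKS <- c("domain", "phylum", "class", "order", "family",
                        "genus", "species"), "none"))
  expect_true(all(diff(ranks) <= 0))
  # lowering max_branch_length never classifies a previously unclassified query
  st <- vapply(c(1.0, 0.3, 0.01), function(mb)
    classify_lca(pl, pkg, classifier_config(max_branch_length = mb))$status, "")
  expect_false(st[1] == "unclassified" && any(st[-1] == "classified"))
})

test_that("batch classification recovers reference lineages and flags paralogs", {
  pkg <- shared_refpkg()
  refs <- setdiff(pkg$tree$tip.label, pkg$outgroup_ids)
  seqs <- stats::setNames(pkg$nuc_alignment[refs], refs)
  cls <- classify_batch(seqs, pkg)
  expect_true(all(cls$status == "classified"))
  for (i in seq_len(nrow(cls))) {
    want <- paste(Filter(nzchar, unlist(
      pkg$taxonomy[pkg$taxonomy$id == cls$query[i],
                   c("domain", "phylum", "class", "order", "family",
                     "genus", "species")])), collapse = ";")
    expect_equal(cls$lineage[i], want)
  }
  # outgroup-derived sequences never get a methylator lineage
  og <- stats::setNames(pkg$nuc_alignment[pkg$outgroup_ids], pkg$outgroup_ids)
  ogc <- classify_batch(og, pkg)
  expect_true(all(ogc$status %in% c("paralog", "filtered_profile",
                                    "filtered_translation", "unclassified")))
  # empty input -> empty table; internal stop -> filtered_translation
  expect_equal(nrow(classify_batch(character(0), pkg)), 0)
  bad <- classify_batch(c(x = "ATGTAACCCGGG"), pkg)
  expect_equal(bad$status, "filtered_translation")
})

test_that("placements export as jplace-compatible JSON", {
  pkg <- make_tiny_refpkg()
  pl <- place_query(pkg$pep_alignment[["A"]], pkg, query_id = "A_self")
  path <- tempfile(fileext = ".jplace")
  write_jplace(pl, pkg, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$version, 3)
  expect_equal(unlist(j$fields),
               c("edge_num", "like_weight_ratio", "branch_length",
                 "pendant_length"))
  expect_equal(j$placements[[1]]$nm[[1]][[1]], "A_self")
})
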