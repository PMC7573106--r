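ADAPTOR <- "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG"

mk_reads <- function(seqs, sample = "s1") {
  data.frame(id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             quality = NA_character_, sample = sample, stringsAsFactors = FALSE)
}

test_that("trimming strips adaptors, truncates and length-filters", {
  set.seed(2)
  long <- random_dna(300)
  short <- random_dna(150)
  with_ad <- paste0(ADAPTOR, random_dna(250))
  out <- trim_and_filter(mk_reads(c(long, short, with_ad)), 201,
                         adaptors = ADAPTOR)
  expect_equal(nrow(out), 2)                       # 150 nt read discarded
  expect_true(all(nchar(out$sequence) == 201))
  expect_equal(out$sequence[1], substr(long, 1, 201))
  expect_equal(out$sequence[2], substr(sub(ADAPTOR, "", with_ad, fixed = TRUE),
                                       1, 201))
  expect_equal(unname(attr(out, "log")), c(3, 2))
  # primer footprint following the adaptor is stripped too
  fv <- expand_primer(degenerate_primer("f", "AAYGTCTGGTGYGCNGCVGG"))$sequence[2]
  core <- random_dna(240)
  out2 <- trim_and_filter(mk_reads(paste0(ADAPTOR, fv, core)), 201,
                          adaptors = ADAPTOR, primer = "AAYGTCTGGTGYGCNGCVGG")
  expect_equal(out2$sequence, substr(core, 1, 201))
})

test_that("dereplication groups exactly, drops singletons, conserves reads", {
  x <- strrep("A", 30); y <- strrep("C", 30); z <- strrep("G", 30)
  reads <- mk_reads(c(x, x, x, y, z, z))
  uni <- dereplicate(reads)
  expect_equal(uni$sequence, c(x, z))              # abundance desc, seq asc
  expect_equal(uni$abundance, c(3L, 2L))
  expect_equal(uni$members[[1]], c("r001", "r002", "r003"))
  expect_equal(sum(attr(uni, "log")[c("retained", "dropped")]), 6)
  uni1 <- dereplicate(reads, min_abundance = 1)
  expect_equal(nrow(uni1), 3)                      # singleton y retained
  expect_true(y %in% uni1$sequence)
})

test_that("chimera detection flags planted crossovers and spares parents", {
  set.seed(9)
  A <- random_dna(201)
  B <- strsplit(A, "")[[1]]
  flip <- sample(201, 40)                          # ~80% identical parents
  for (i in flip) B[i] <- sample(setdiff(c("A", "C", "G", "T"), B[i]), 1)
  B <- paste(B, collapse = "")
  chim <- paste0(substr(A, 1, 100), substr(B, 101, 201))
  uni <- data.frame(sequence = c(A, B, chim), abundance = c(10L, 10L, 2L),
                    stringsAsFactors = FALSE)
  det <- detect_chimeras(uni, parents = c(A, B), mode = "reference")
  expect_false(det$is_chimera[1])                  # a parent is never flagged
  expect_false(det$is_chimera[2])
  expect_true(det$is_chimera[3])
  expect_gte(det$best_model_identity[3], 0.999)    # exact two-parent model
  # brute force over all crossover points agrees with the model identity
  brute <- max(vapply(1:200, function(x)
    mean(strsplit(paste0(substr(A, 1, x), substr(B, x + 1, 201)), "")[[1]] ==
           strsplit(chim, "")[[1]]), numeric(1)))
  expect_equal(det$best_model_identity[3], brute)
  # de novo mode: abundance skew gates parent eligibility
  det2 <- detect_chimeras(uni, mode = "denovo", skew = 2)
  expect_true(det2$is_chimera[3])
  expect_false(any(det2$is_chimera[1:2]))
  # nearly identical parents cannot produce a flaggable crossover
  B99 <- A; substr(B99, 50, 50) <- "A"; substr(B99, 150, 151) <- "AA"
  chim99 <- paste0(substr(A, 1, 100), substr(B99, 101, 201))
  det3 <- detect_chimeras(data.frame(sequence = chim99, abundance = 1L),
                          parents = c(A, B99), mode = "reference")
  expect_false(det3$is_chimera)
})

test_that("greedy clustering satisfies centroid invariants against all-pairs identities", {
  set.seed(13)
  for (rep in 1:8) {
    templates <- replicate(3, random_dna(120))
    seqs <- vapply(1:15, function(i) {
      ch <- strsplit(templates[(i %% 3) + 1], "")[[1]]
      for (p in sample(120, sample(0:8, 1)))
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    }, "")
    uni <- dereplicate(mk_reads(rep(seqs, times = sample(1:4, 15, TRUE))),
                       min_abundance = 1)
    otus <- cluster_greedy(uni, identity = 0.90)
    # members >= cutoff to their centroid; centroids pairwise < cutoff
    for (k in seq_len(nrow(otus))) {
      for (m in otus$members[[k]])
        expect_gte(oracle_global_identity(m, otus$centroid[k]), 0.90)
    }
    if (nrow(otus) > 1) {
      for (i in 1:(nrow(otus) - 1)) for (j in (i + 1):nrow(otus))
        expect_lt(oracle_global_identity(otus$centroid[i], otus$centroid[j]),
                  0.90)
    }
  }
})

test_that("clustering handles identical and sub-cutoff inputs; peptide space works", {
  x <- strrep("ACGTA", 24)
  uni <- data.frame(sequence = rep(x, 3), abundance = c(3L, 2L, 1L))
  expect_equal(nrow(cluster_greedy(dereplicate(mk_reads(rep(x, 3)),
                                               min_abundance = 1))), 1)
  set.seed(3)
  a <- random_dna(120)
  b <- strsplit(a, "")[[1]]
  for (p in sample(120, 18)) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  uni2 <- data.frame(sequence = c(a, paste(b, collapse = "")),
                     abundance = c(2L, 2L), stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_greedy(uni2, identity = 0.90)), 2)
  expect_equal(nrow(cluster_greedy(uni2[0, ], identity = 0.90)), 0)
  pep <- cluster_greedy(uni2, identity = 0.95, on = "peptide")
  expect_true(nrow(pep) >= 1)
})

test_that("read mapping assigns to best centroid and conserves counts", {
  set.seed(21)
  c1 <- random_dna(100); c2 <- random_dna(100)
  otus <- data.frame(otu = c("OTU_001", "OTU_002"), centroid = c(c1, c2),
                     stringsAsFactors = FALSE)
  near1 <- c1; substr(near1, 5, 5) <- "A"
  reads <- rbind(mk_reads(c(c1, near1, c2), sample = "s1"),
                 mk_reads(c(c2, random_dna(100)), sample = "s2"))
  m <- map_reads(reads, otus, identity = 0.90)
  expect_equal(m$table["OTU_001", "s1"], 2L)
  expect_equal(m$table["OTU_002", "s2"], 1L)
  expect_equal(unname(m$unmapped["s2"]), 1L)
  for (s in c("s1", "s2"))
    expect_equal(sum(m$table[, s]) + m$unmapped[[s]], sum(reads$sample == s))
})

test_that("the pipeline is deterministic and recovers error-free templates", {
  sim <- shared_sim()
  taxa <- pick_taxa(sim, 3)
  cfg <- simulation_config(composition = stats::setNames(c(0.5, 0.3, 0.2), taxa),
                           n_reads = 300, seed = 19)
  run <- simulate_amplicon_run(sim, cfg)
  go <- function() run_pipeline(run$reads, adaptors = cfg$adaptor,
                                primer = cfg$fwd_primer, chimera_filter = FALSE)
  r1 <- go(); r2 <- go()
  expect_identical(r1$otu_table, r2$otu_table)
  expect_equal(nrow(r1$otus), 3)                   # templates < 90% identical
  expect_equal(sort(unname(r1$otu_table[, 1])), sort(c(150L, 90L, 60L)))
  expect_equal(sum(r1$otu_table), 300 - sum(r1$log$unmapped))
})
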