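PF <- "AAYGTCTGGTGYGCNGCVGG"   # forward primer, degeneracy 48
PR <- "CAGGCNCCGCAYTCSATRCA"   # reverse primer, degeneracy 32

plant <- function(core, upstream = 30, downstream = 40, seed = 1) {
  set.seed(seed)
  paste0(random_dna(upstream), core, random_dna(downstream))
}

test_that("binding sites honor mismatch counts and 3'-end protection", {
  variant <- expand_primer(degenerate_primer("f", PF))$sequence[1]
  tgt <- plant(variant)
  hit <- find_binding_sites(PF, tgt, match_policy(2), "forward")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 31)
  expect_equal(hit$end, 50)
  expect_equal(hit$mismatch_count, 0)

  # one substitution 3 bases from the 3' end (offset 2, protected) -> no site
  mut3p <- variant
  pos <- nchar(variant) - 2
  substr(mut3p, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     iupac_sets()[[substr(PF, pos, pos)]])[1]
  expect_equal(nrow(find_binding_sites(PF, plant(mut3p), match_policy(2))), 0)

  # same substitution 3 bases from the 5' end -> one site with 1 mismatch
  mut5p <- variant
  b <- substr(variant, 3, 3)
  repl <- setdiff(c("A", "C", "G", "T"),
                  iupac_sets()[[substr(PF, 3, 3)]])[1]
  substr(mut5p, 3, 3) <- repl
  hit5 <- find_binding_sites(PF, plant(mut5p), match_policy(2))
  expect_equal(hit5$mismatch_count, 1)
  expect_equal(hit5$mismatch_offsets, "17")

  # primer longer than target is an empty result, not an error
  expect_equal(nrow(find_binding_sites(PF, "ACGT", match_policy(2))), 0)
  expect_error(find_binding_sites(PF, "ACGTQ", match_policy(2)), "non-ACGTN")
})

test_that("reverse orientation reports sense-strand coordinates with left-end protection", {
  rvar <- expand_primer(degenerate_primer("r", PR))$sequence[4]
  tgt <- plant(reverse_complement(rvar), upstream = 25, downstream = 55)
  hit <- find_binding_sites(PR, tgt, match_policy(0), "reverse")
  expect_equal(hit$strand, "-")
  expect_equal(hit$start, 26)
  expect_equal(hit$end, 45)
  # mutate the FIRST footprint base on the sense strand = primer 3' terminus
  tgt2 <- tgt
  substr(tgt2, 26, 26) <- setdiff(c("A", "C", "G", "T"), substr(tgt, 26, 26))[1]
  expect_equal(nrow(find_binding_sites(PR, tgt2, match_policy(2), "reverse")), 0)
})

test_that("binding sites agree with the brute-force all-variant oracle", {
  set.seed(11)
  for (i in 1:100) {
    primer <- degenerate_primer("p", random_primer(sample(10:20, 1), sample(1:3, 1)))
    n <- sample(60:400, 1)
    tgt <- random_dna(n)
    if (i %% 2 == 0) {  # plant a footprint to guarantee some hits
      v <- expand_primer(primer)$sequence[1]
      at <- sample(n - nchar(v), 1)
      ori <- if (i %% 4 == 0) v else reverse_complement(v)
      substr(tgt, at, at + nchar(v) - 1) <- ori
    }
    pol <- match_policy(sample(0:3, 1), sample(0:6, 1))
    for (ori in c("forward", "reverse")) {
      got <- find_binding_sites(primer, tgt, pol, ori)
      want <- oracle_binding_sites(primer, if (ori == "forward") tgt else
        reverse_complement(tgt), pol, "forward")
      # map oracle (run in scan space) back to sense coordinates
      if (ori == "reverse" && nrow(want))
        want$start <- sort(nchar(tgt) - (want$start + nchar(primer$sequence) - 1) + 1)
      expect_equal(got$start, sort(want$start))
      expect_equal(sum(got$mismatch_count), sum(want$mismatch_count))
    }
  }
})

test_that("efficiency counts covered records and is monotone in mismatches", {
  v <- expand_primer(degenerate_primer("f", PF))$sequence
  lib <- target_library(paste0("s", 1:4),
                        c(plant(v[1], seed = 1), plant(v[10], seed = 2),
                          plant(v[20], seed = 3), random_dna(90)),
                        taxonomy = data.frame(id = paste0("s", 1:4),
                                              phylum = c("P1", "P1", "P2", "P2")))
  eff <- primer_efficiency(PF, lib, match_policy(0))
  expect_equal(eff$efficiency, 0.75)
  expect_equal(eff$per_clade$fraction[eff$per_clade$clade == "P1"], 1)
  # a library of padded own variants has efficiency 1
  lib2 <- target_library(paste0("v", 1:5),
                         vapply(1:5, function(i) plant(v[i], seed = i), ""))
  expect_equal(primer_efficiency(PF, lib2, match_policy(0))$efficiency, 1)
  # tightening max_mismatches never increases efficiency
  e <- vapply(0:2, function(m)
    primer_efficiency(PF, lib, match_policy(m))$efficiency, numeric(1))
  expect_true(all(diff(e) >= 0))
  expect_error(primer_efficiency(PF, lib[0, ], match_policy(0)), "non-empty")
})

test_that("specificity screen reports nested per-mismatch-level hits", {
  decoys <- make_paralog_library(100, PR, near_miss_fraction = 0.06, seed = 21)
  spec <- specificity_screen(PR, decoys, match_policy(2))
  expect_equal(spec$count[spec$max_mismatches == 0], 0)
  expect_equal(spec$fraction[spec$max_mismatches == 2], 0.06)
  expect_true(all(diff(spec$count) >= 0))
  expect_error(specificity_screen(PR, decoys[0, ], match_policy(2)), "non-empty")
})

test_that("redundancy matches the published worked examples", {
  # 46 of 96 variants present -> 50 unmatched -> 52.1%
  v96 <- expand_primer(degenerate_primer("r", "CABGCNCCRCAYTCCATRCA"))
  lib96 <- target_library(paste0("s", 1:46),
                          vapply(1:46, function(i) plant(v96$sequence[i], seed = i), ""))
  red96 <- primer_redundancy("CABGCNCCRCAYTCCATRCA", lib96)
  expect_equal(red96$count, 50)
  expect_equal(red96$percent, 52.1)
  # 18 of 32 present -> 14 unmatched -> 43.8%
  v32 <- expand_primer(degenerate_primer("r", PR))
  lib32 <- target_library(paste0("s", 1:18),
                          vapply(1:18, function(i) plant(v32$sequence[i], seed = i), ""))
  red32 <- primer_redundancy(PR, lib32)
  expect_equal(red32$count, 14)
  expect_equal(red32$percent, 43.8)
  # all variants present -> 0 (and matched + unmatched == degeneracy)
  liball <- target_library(paste0("s", 1:32),
                           vapply(1:32, function(i) plant(v32$sequence[i], seed = i), ""))
  redall <- primer_redundancy(PR, liball)
  expect_equal(redall$count, 0)
  expect_equal(redall$percent, 0)
  expect_equal(length(red32$matched_ids) + red32$count, 32)
})

test_that("equal-distribution threshold is 100/degeneracy at printed precision", {
  expect_equal(equal_distribution_threshold(32), 3.13)
  expect_equal(equal_distribution_threshold(96), 1.04)
  expect_equal(equal_distribution_threshold(1), 100)
  expect_equal(equal_distribution_threshold(48), 2.08)
  expect_error(equal_distribution_threshold(0), ">= 1")
})

test_that("occurrence tally counts footprint-bearing sequences once each", {
  p <- degenerate_primer("p", "ACGTACGTRY")  # degeneracy 4, threshold 25
  v <- expand_primer(p)$sequence
  obs <- c(rep(plant(v[1], 5, 5, seed = 1), 50), rep(plant(v[3], 4, 6, seed = 2), 40),
           rep(random_dna(40), 10))
  tal <- occurrence_tally(p, obs)
  expect_equal(tal$count, c(50L, 0L, 40L, 0L))
  expect_equal(attr(tal, "n_with_footprint"), 90)
  expect_equal(tal$percent[1], 100 * 50 / 90)
  expect_equal(sum(tal$count), 90)          # conservation
  expect_equal(attr(tal, "threshold"), 25)
  expect_equal(tal$below_threshold, c(FALSE, TRUE, FALSE, TRUE))
  # uniform usage sits exactly at the threshold: nothing is flagged
  uni <- occurrence_tally(p, vapply(1:4, function(i) plant(v[i], seed = i), ""))
  expect_false(any(uni$below_threshold))
  # empty observed set -> all zeros
  expect_equal(occurrence_tally(p, character(0))$count, rep(0L, 4))
})

test_that("conservation profile categorizes mean pairwise identity", {
  prof <- conservation_profile(c("AAAA", "AACC", "CACG", "CACT"))
  expect_equal(prof$mean_pairwise_identity, c(33.3, 100, 50, 0))
  expect_equal(prof$category, c("mid", "full", "mid", "low"))
  expect_error(conservation_profile(c("AA", "AAA")), "equal lengths")
  expect_error(conservation_profile("AA"), "at least 2")
})

test_that("positional edits reproduce the reverse-primer redesign", {
  old <- degenerate_primer("uni-R", "CABGCNCCRCAYTCCATRCA")
  new <- apply_edits(old, c("3" = "G", "9" = "G", "15" = "S"))
  expect_equal(new$sequence, "CAGGCNCCGCAYTCSATRCA")
  expect_equal(attr(new, "degeneracy_before"), 96)
  expect_equal(attr(new, "degeneracy_after"), 32)
  expect_equal(apply_edits(old, c())$sequence, old$sequence)
  same <- apply_edits(old, c("3" = "B"))
  expect_equal(attr(same, "degeneracy_after"), 96)
  expect_error(apply_edits(old, c("25" = "G")), "out of range")
})

test_that("data-driven reduction restricts positions to observed bases", {
  p <- degenerate_primer("p", "ACBTACGTRY")
  v <- expand_primer(p)
  # library uses only variants with G at the degenerate position 3
  used <- v$sequence[substr(v$sequence, 3, 3) == "G"]
  lib <- target_library(paste0("s", seq_along(used)),
                        vapply(seq_along(used), function(i) plant(used[i], seed = i), ""))
  red <- reduce_degeneracy(p, lib, min_base_freq = 0.05)
  expect_equal(substr(red$primer$sequence, 3, 3), "G")
  expect_lte(red$degeneracy_after, red$degeneracy_before)
  # a zero floor keeps the primer unchanged
  red0 <- reduce_degeneracy(p, lib, min_base_freq = 0)
  expect_equal(red0$primer$sequence, p$sequence)
  expect_error(reduce_degeneracy(p, target_library("x", random_dna(50)), 0.1),
               "no exact primer footprints")
})

test_that("equimolar subset drops variants below the floor in every table", {
  p <- degenerate_primer("uni-32R", PR)
  v <- expand_primer(p)
  mk <- function(low_idx) data.frame(id = v$id,
                                     percent = ifelse(v$index %in% low_idx, 0.1, 5))
  # six variants below floor everywhere -> 26 remain
  six <- c(5, 7, 9, 15, 17, 21)
  expect_equal(select_equimolar_subset(p, list(mk(six), mk(six)), 1)$n_kept, 26)
  # floor 0 keeps all 32
  expect_equal(select_equimolar_subset(p, list(mk(six)), 0)$n_kept, 32)
  # ten below floor everywhere -> 22; a variant rescued by one table is kept
  ten <- 1:10
  expect_equal(select_equimolar_subset(p, list(mk(ten), mk(ten)), 1)$n_kept, 22)
  expect_equal(select_equimolar_subset(p, list(mk(ten), mk(2:10)), 1)$n_kept, 23)
  expect_error(select_equimolar_subset(p, list(mk(six)[-1, ]), 1), "cover")
})

test_that("amplicon prediction pairs forward sites with downstream reverse sites", {
  fv <- expand_primer(degenerate_primer("f", PF))$sequence[1]
  rv <- expand_primer(degenerate_primer("r", PR))$sequence[1]
  set.seed(5)
  mid <- random_dna(950 - nchar(fv) - nchar(rv))
  tgt <- paste0(random_dna(60), fv, mid, reverse_complement(rv), random_dna(30))
  amp <- predict_amplicons(PF, PR, tgt, match_policy(0))
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 950)
  expect_equal(nchar(amp$sequence), 950)
  # forward site only -> empty
  expect_equal(nrow(predict_amplicons(PF, PR, plant(fv), match_policy(0))), 0)
  # reverse footprint upstream of the forward footprint -> empty
  tgt_rev <- paste0(random_dna(30), reverse_complement(rv), random_dna(100), fv,
                    random_dna(30))
  expect_equal(nrow(predict_amplicons(PF, PR, tgt_rev, match_policy(0),
                                      c(1, 5000))), 0)
})
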