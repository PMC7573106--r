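# Fixture generators: clade-structured reference libraries with planted
# primer footprints, paralog decoys, and mock-community amplicon runs with
# controlled error and chimera rates.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Defaults encode the study conditions used throughout the package tests:
#' a clade-structured reference library around the broad-range hgcAB primer
#' pair, and mock-community runs with preset compositions.
#'
#' @param n_clades Number of clades (phyla) in the reference library.
#' @param taxa_per_clade Records per clade.
#' @param between_clade_divergence Per-site substitution divergence applied
#'   when deriving each clade ancestor from the root gene (default 0.15).
#' @param within_clade_divergence Divergence of each taxon from its clade
#'   ancestor (default 0.03).
#' @param fwd_primer,rev_primer IUPAC primer strings (5'->3'); defaults are
#'   the broad-range forward primer and the 32-fold degenerate reverse.
#' @param fwd_usage,rev_usage Oligo-variant usage weights when planting
#'   footprints: `"uniform"` or a numeric weight vector of length equal to
#'   the primer degeneracy.
#' @param composition Named proportions (library record ids) for
#'   mock-community runs; must sum to 1.
#' @param n_reads Reads per simulated run (default 2000).
#' @param error_rate I.i.d. per-base substitution probability (default 0).
#' @param indel_rate I.i.d. per-base indel probability (default 0).
#' @param chimera_rate Fraction of reads formed as two-parent single
#'   crossover chimeras (default 0).
#' @param adaptor 5' adaptor string prefixed to every read.
#' @param seed Integer seed recorded in all outputs.
#' @return List with class `simulation_config`.
#' @export
simulation_config <- function(n_clades = 6L, taxa_per_clade = 4L,
                              between_clade_divergence = 0.15,
                              within_clade_divergence = 0.03,
                              fwd_primer = "AAYGTCTGGTGYGCNGCVGG",
                              rev_primer = "CAGGCNCCGCAYTCSATRCA",
                              fwd_usage = "uniform", rev_usage = "uniform",
                              composition = NULL, n_reads = 2000L,
                              error_rate = 0, indel_rate = 0,
                              chimera_rate = 0,
                              adaptor = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
                              seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 1, chimera_rate >= 0,
            chimera_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  if (!is.null(composition) && abs(sum(composition) - 1) > 1e-6)
    stop("composition proportions must sum to 1")
  structure(as.list(environment()), class = "simulation_config")
}

#' Mock-community composition presets
#'
#' The two as-printed three-member compositions used for mock-community
#' validation: combo1 = 41/50/9 and combo2 = 59/7/35 (percent read
#' proportions). The combo2 percentages sum to 101 as printed; they are
#' normalized here so each preset is a proper proportion vector with the
#' printed ratios.
#'
#' @return Named list of numeric proportion vectors (unnamed; attach library
#'   record ids before use).
#' @export
mock_presets <- function() {
  list(combo1 = c(0.41, 0.50, 0.09),
       combo2 = c(0.59, 0.07, 0.35) / 1.01)
}

.random_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# substitute each position independently at `rate`, never into the same base
.mutate <- function(chars, rate, protect = integer(0)) {
  hit <- which(stats::runif(length(chars)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) chars[i] <- sample(setdiff(.BASES, chars[i]), 1)
  chars
}

# force codon 1 to ATG and break any in-frame stop codon (middle base -> C)
.fix_orf <- function(chars, start, end) {
  chars[start:(start + 2)] <- c("A", "T", "G")
  for (s in seq(start, end - 2, 3)) {
    if (paste(chars[s:(s + 2)], collapse = "") %in% .STOPS) chars[s + 1] <- "C"
  }
  chars
}

.draw_variant <- function(variants, usage) {
  if (identical(usage, "uniform")) {
    variants[sample(nrow(variants), 1), ]
  } else {
    stopifnot(length(usage) == nrow(variants))
    variants[sample(nrow(variants), 1, prob = usage), ]
  }
}

.aa_diff <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Generate a clade-structured reference library with planted primer sites
#'
#' A root gene is diverged into clades and taxa at the configured
#' divergences. Every record carries a forward primer footprint, a 201 nt
#' region (open reading frame: start codon first, no in-frame stops)
#' immediately downstream, and a reverse primer footprint placed so the
#' predicted product is 950 nt; footprint variants are drawn from the
#' configured usage distributions. Region peptides are forced to differ by
#' at least 3 residues between records (a curated, dereplicated reference
#' library). Layout (1-based): forward footprint 101-120, region 121-321,
#' reverse footprint 1031-1050.
#'
#' @param config A [simulation_config()].
#' @return List: `library` (taxonomy-annotated data.frame, role
#'   `reference_gene`), `truth` (per-record planted variants), `root`
#'   (root gene string), `coords` (named layout positions), `config`.
#' @export
make_reference_library <- function(config = simulation_config()) {
  set.seed(config$seed)
  fwd <- degenerate_primer("fwd", config$fwd_primer)
  rev <- degenerate_primer("rev", config$rev_primer)
  fv <- expand_primer(fwd)
  rv <- expand_primer(rev)
  Lf <- nchar(config$fwd_primer)
  Lr <- nchar(config$rev_primer)
  up <- 100L
  fwd_start <- up + 1L
  region_start <- fwd_start + Lf
  region_end <- region_start + 200L
  # amplicon (forward footprint start .. reverse footprint end) = 950 nt
  rev_end <- fwd_start + 950L - 1L
  rev_start <- rev_end - Lr + 1L
  gene_len <- rev_end + 50L
  if (config$within_clade_divergence > 0.4 ||
      config$between_clade_divergence > 0.4)
    stop("divergence settings too high: planted footprints would be destroyed")
  root <- strsplit(.random_seq(gene_len), "")[[1]]
  root <- .fix_orf(root, region_start, region_end)
  footprint_pos <- c(fwd_start:(fwd_start + Lf - 1L), rev_start:rev_end)
  ids <- character(0)
  seqs <- list()
  tax <- list()
  truth <- list()
  peps <- character(0)
  for (cl in seq_len(config$n_clades)) {
    anc <- .mutate(root, config$between_clade_divergence, footprint_pos)
    for (tx in seq_len(config$taxa_per_clade)) {
      chars <- .mutate(anc, config$within_clade_divergence, footprint_pos)
      chars <- .fix_orf(chars, region_start, region_end)
      # enforce >= 3 residue differences to every earlier record's region
      pep <- translate_frame0(paste(chars[region_start:region_end],
                                    collapse = ""))
      tries <- 0L
      while (length(peps) && min(vapply(peps, .aa_diff, 0, b = pep)) < 3L) {
        tries <- tries + 1L
        if (tries > 100L) stop("could not generate distinct region peptides")
        codon <- sample(seq(region_start + 3L, region_end - 2L, 3L), 1)
        chars[codon:(codon + 1L)] <- sample(.BASES, 2, replace = TRUE)
        chars <- .fix_orf(chars, region_start, region_end)
        pep <- translate_frame0(paste(chars[region_start:region_end],
                                      collapse = ""))
      }
      peps <- c(peps, pep)
      fvar <- .draw_variant(fv, config$fwd_usage)
      rvar <- .draw_variant(rv, config$rev_usage)
      chars[fwd_start:(fwd_start + Lf - 1L)] <-
        strsplit(fvar$sequence, "")[[1]]
      chars[rev_start:rev_end] <-
        strsplit(reverse_complement(rvar$sequence), "")[[1]]
      id <- sprintf("ref_c%02d_t%02d", cl, tx)
      ids <- c(ids, id)
      seqs[[id]] <- paste(chars, collapse = "")
      tax[[id]] <- data.frame(
        id = id, domain = "Bacteria",
        phylum = sprintf("Phylum_%02d", cl),
        class = sprintf("Class_%02d", cl),
        order = sprintf("Order_%02d", cl),
        family = sprintf("Family_%02d", cl),
        genus = sprintf("Genus_%02d_%d", cl, ceiling(tx / 2)),
        species = sprintf("Species_%02d_%02d", cl, tx),
        stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(id = id, clade = cl,
                                fwd_variant_id = fvar$id,
                                rev_variant_id = rvar$id,
                                stringsAsFactors = FALSE)
    }
  }
  lib <- target_library(ids, unlist(seqs[ids]), role = "reference_gene",
                        taxonomy = do.call(rbind, tax))
  list(library = lib, truth = do.call(rbind, truth),
       root = paste(root, collapse = ""),
       coords = c(fwd_start = fwd_start, region_start = region_start,
                  region_end = region_end, rev_start = rev_start,
                  rev_end = rev_end, gene_len = gene_len),
       config = config)
}

#' Generate a paralog decoy library
#'
#' Random sequences carrying a degraded reverse-primer binding site.
#' By default every decoy has 3 mismatches to the primer inside its
#' protected 3' window, so neither exact nor protected mismatch-tolerant
#' matching fires. A `near_miss_fraction` of decoys instead carries exactly
#' 2 mismatches outside the protected window (never an exact site, but a
#' 2-mismatch screen hits them).
#'
#' @param n Number of decoys.
#' @param rev_primer IUPAC reverse primer (5'->3').
#' @param near_miss_fraction Fraction of decoys with 2-mismatch sites
#'   (default 0).
#' @param length Decoy length (default 400).
#' @param protected Protected 3' window width (default 5).
#' @param seed Integer seed.
#' @return Library data.frame with role `paralog`; attribute `near_miss_ids`
#'   names the planted near-miss decoys.
#' @export
make_paralog_library <- function(n, rev_primer = "CAGGCNCCGCAYTCSATRCA",
                                 near_miss_fraction = 0, length = 400L,
                                 protected = 5L, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  primer_chars <- strsplit(toupper(rev_primer), "")[[1]]
  L <- base::length(primer_chars)
  sets <- iupac_sets()[primer_chars]
  n_near <- round(n * near_miss_fraction)
  ids <- sprintf("paralog_%03d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i) {
    chars <- strsplit(.random_seq(length), "")[[1]]
    # plant a concrete variant of the primer, then break it
    site <- vapply(sets, function(s) sample(s, 1), "")
    if (i <= n_near) {
      # two mismatches strictly outside the protected 3' window
      pos <- sample(seq_len(L - protected), 2)
    } else {
      # three mismatches inside the protected window (offsets 0..protected-1)
      pos <- L - sample(seq_len(protected), 3) + 1L
    }
    for (p in pos) site[p] <- sample(setdiff(.BASES, sets[[p]]), 1)
    at <- 150L
    chars[at:(at + L - 1L)] <-
      strsplit(reverse_complement(paste(site, collapse = "")), "")[[1]]
    paste(chars, collapse = "")
  }, "")
  out <- target_library(ids, seqs, role = "paralog")
  attr(out, "near_miss_ids") <- ids[seq_len(n_near)]
  out
}

#' Build a reference package from a simulated library
#'
#' Extracts the 201 nt region alignment (ungapped; the simulated records
#' are positionally homologous by construction), translates it, appends
#' diverged outgroup records standing in for non-methylator carbon monoxide
#' dehydrogenase paralogs, builds the profile, and infers a
#' neighbor-joining tree from peptide p-distances rooted on the outgroup.
#'
#' @param sim Output of [make_reference_library()].
#' @param name Package name.
#' @param n_outgroup Number of outgroup records (default 2).
#' @param outgroup_divergence Divergence of outgroups from the root region
#'   (default 0.4).
#' @param seed Seed for outgroup generation (default: the sim's seed + 1).
#' @return A `refpkg`.
#' @export
make_refpkg_from_library <- function(sim, name = "synthetic_201",
                                     n_outgroup = 2L,
                                     outgroup_divergence = 0.4,
                                     seed = NULL) {
  if (is.null(seed)) seed <- sim$config$seed + 1L
  set.seed(seed)
  rs <- sim$coords[["region_start"]]
  re <- sim$coords[["region_end"]]
  nuc <- stats::setNames(substr(sim$library$sequence, rs, re), sim$library$id)
  root_region <- strsplit(substr(sim$root, rs, re), "")[[1]]
  out_ids <- sprintf("outgroup_%02d", seq_len(n_outgroup))
  for (i in seq_len(n_outgroup)) {
    chars <- .mutate(root_region, outgroup_divergence)
    chars <- .fix_orf(chars, 1L, base::length(chars))
    nuc[out_ids[i]] <- paste(chars, collapse = "")
  }
  pep <- vapply(nuc, translate_frame0, "")
  substr(pep, 1, 1) <- "M"
  tax <- sim$library[, c("id", .RANKS)]
  for (i in seq_len(n_outgroup)) {
    tax <- rbind(tax, data.frame(
      id = out_ids[i], domain = "Bacteria", phylum = "CODH_paralogs",
      class = "CODH", order = "", family = "", genus = "",
      species = sprintf("CODH_sp_%02d", i), stringsAsFactors = FALSE))
  }
  pmat <- do.call(rbind, strsplit(pep, ""))
  n <- nrow(pmat)
  d <- matrix(0, n, n, dimnames = list(names(pep), names(pep)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- mean(pmat[i, ] != pmat[j, ])
  tree <- build_nj_tree(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree <- root_tree(tree, out_ids)
  region <- region_spec("201", sim$library$id[1], rs - rs + 1L, re - rs + 1L)
  region$start <- 1L
  region$end <- re - rs + 1L
  reference_package(name, region, nuc, pep, tree, tax,
                    outgroup_ids = out_ids, seed = seed)
}

# largest-remainder rounding of n * proportions to integers summing to n
.apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(-(raw - base))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Simulate a mock-community amplicon run
#'
#' Draws read templates according to the composition (largest-remainder
#' apportionment, so realized counts match the composition exactly),
#' prefixes the 5' adaptor, applies i.i.d. substitutions at the error rate
#' (and indels at the indel rate, if configured), and forms two-parent
#' single-crossover chimeras at the chimera rate (breakpoints in the
#' interior of the read so both parents contribute). Each read covers the
#' adaptor, the forward primer footprint, the 201 nt region and downstream
#' sequence (300 nt + adaptor in total).
#'
#' @param sim Output of [make_reference_library()].
#' @param config A [simulation_config()] whose `composition` names library
#'   record ids.
#' @param sample Sample label (default "mock").
#' @return List: `reads` (data.frame `id`, `sequence`, `quality`, `sample`),
#'   `truth` (data.frame `id`, `taxon`, `is_chimera`, `parent2`,
#'   `n_errors`), `config`.
#' @export
simulate_amplicon_run <- function(sim, config, sample = "mock") {
  if (is.null(config$composition)) stop("config$composition is required")
  comp <- config$composition
  missing <- setdiff(names(comp), sim$library$id)
  if (base::length(missing))
    stop("composition taxa not in library: ", paste(missing, collapse = ", "))
  set.seed(config$seed)
  counts <- .apportion(config$n_reads, comp)
  fwd_start <- sim$coords[["fwd_start"]]
  core_len <- 300L
  cores <- stats::setNames(substr(sim$library$sequence, fwd_start,
                                  fwd_start + core_len - 1L), sim$library$id)
  taxon <- rep(names(counts), counts)
  n <- base::length(taxon)
  is_chim <- stats::runif(n) < config$chimera_rate
  parent2 <- rep(NA_character_, n)
  seqs <- character(n)
  nerr <- integer(n)
  for (i in seq_len(n)) {
    core <- strsplit(cores[[taxon[i]]], "")[[1]]
    if (is_chim[i] && base::length(names(comp)) > 1) {
      other <- sample(setdiff(names(comp), taxon[i]), 1)
      parent2[i] <- other
      # breakpoint inside the 201 nt analyzed region (core positions 21-221),
      # at least 25 bases from either region edge, so planted chimeras stay
      # chimeric in the trimmed data the detector sees
      bp <- sample(45:195, 1)
      core2 <- strsplit(cores[[other]], "")[[1]]
      core <- c(core[1:bp], core2[(bp + 1L):core_len])
    }
    if (config$error_rate > 0) {
      hit <- which(stats::runif(base::length(core)) < config$error_rate)
      for (p in hit) core[p] <- sample(setdiff(.BASES, core[p]), 1)
      nerr[i] <- base::length(hit)
    }
    if (config$indel_rate > 0) {
      hit <- which(stats::runif(base::length(core)) < config$indel_rate)
      for (p in rev(hit)) {
        if (stats::runif(1) < 0.5) {
          core <- append(core, sample(.BASES, 1), after = p)
        } else {
          core <- core[-p]
        }
      }
      nerr[i] <- nerr[i] + base::length(hit)
    }
    seqs[i] <- paste0(config$adaptor, paste(core, collapse = ""))
  }
  reads <- data.frame(
    id = sprintf("read_%06d", seq_len(n)),
    sequence = seqs,
    quality = strrep("I", nchar(seqs)),
    sample = sample, stringsAsFactors = FALSE)
  truth <- data.frame(id = reads$id, taxon = taxon, is_chimera = is_chim,
                      parent2 = parent2, n_errors = nerr,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, config = config)
}
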