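# Fixtures built in code at test time.

# Hand-built 5-leaf reference package:
#   A, B  sister species in two genera of one family (clade X)
#   C     second family in clade X
#   D     distant leaf on a pendant edge of length 1.2 (branch-length rule)
#   OG    non-methylator paralog outgroup
# Peptides are positionally aligned, length 21; A and B differ at exactly
# two positions so an intermediate query is equidistant from both.
make_tiny_refpkg <- function() {
  base <- "MKTAYIAKQRQISFVKSHFSR"
  subst <- function(s, pos, ch) {
    for (i in seq_along(pos)) substr(s, pos[i], pos[i]) <- ch[i]
    s
  }
  pep <- c(
    A  = subst(base, c(5, 9), c("L", "N")),
    B  = subst(base, c(5, 9), c("V", "D")),
    C  = subst(base, c(3, 7, 11, 15), c("S", "G", "W", "E")),
    D  = subst(base, c(2, 6, 10, 14, 18), c("P", "P", "P", "P", "P")),
    OG = subst(base, c(1, 4, 8, 12, 16, 20), c("G", "G", "G", "G", "G", "G"))
  )
  # arbitrary codon back-translation (length 63) just to fill the slot
  codon <- c(M = "ATG", K = "AAA", T = "ACT", A = "GCT", Y = "TAT", I = "ATT",
             Q = "CAA", R = "CGT", S = "TCT", F = "TTT", V = "GTT", H = "CAT",
             L = "CTT", N = "AAT", D = "GAT", G = "GGT", W = "TGG", E = "GAA",
             P = "CCT")
  nuc <- vapply(pep, function(p)
    paste(codon[strsplit(p, "")[[1]]], collapse = ""), "")
  tree <- ape::read.tree(
    text = "(((A:0.05,B:0.05):0.2,C:0.3):0.2,D:1.2,OG:0.8);")
  tree <- root_tree(tree, "OG")
  tax <- data.frame(
    id = c("A", "B", "C", "D", "OG"),
    domain = "Bacteria",
    phylum = c("PhyX", "PhyX", "PhyX", "PhyD", "CODH_paralogs"),
    class = c("ClX", "ClX", "ClX", "ClD", "CODH"),
    order = c("OrX", "OrX", "OrX", "OrD", ""),
    family = c("FamX", "FamX", "FamX2", "FamD", ""),
    genus = c("GenA", "GenB", "GenC", "GenD", ""),
    species = c("SpA", "SpB", "SpC", "SpD", "CODH_sp"),
    stringsAsFactors = FALSE)
  reference_package("tiny", region_spec("201", "A", 1, 63),
                    nuc, pep, tree, tax, outgroup_ids = "OG")
}

# Default synthetic world shared by heavier tests (cached per session).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_reference_library(simulation_config(seed = 101))
    cache
  }
})

shared_refpkg <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_refpkg_from_library(shared_sim())
    cache
  }
})

# first record id of each of the first k phyla
pick_taxa <- function(sim, k) sim$library$id[!duplicated(sim$library$phylum)][seq_len(k)]
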