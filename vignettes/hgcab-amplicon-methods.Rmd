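---
title: "Degenerate primer evaluation and placement-based hgcA profiling: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degenerate primer evaluation and placement-based hgcA profiling: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgcamplicon)
```

# Scope

`hgcamplicon` audits degenerate PCR primers against reference gene libraries
and turns functional-gene amplicon reads into taxonomic profiles by
phylogenetic placement. It is built around the *hgcAB* mercury-methylation
marker — a broad-range forward primer binding the conserved HgcA cap-helix
coding region and a reverse primer binding the `C(M/I)ECGA` ferredoxin motif
of *hgcB* — but every operation is generic over IUPAC primer strings and
7-rank taxonomies.

This vignette records the models the package implements, the tunable
parameters and their defaults, and the design decisions taken where the
design was genuinely open.

# Primer algebra and audit statistics

A degenerate primer written with IUPAC ambiguity codes stands for a mixture
of concrete oligonucleotides. Its *degeneracy* is the product over positions
of each code's base-set size; `expand_primer()` enumerates the variants in a
fixed order (per-position alternatives A < C < G < T, rightmost position
varying fastest) so variant ids such as `uni-32R-05` are reproducible across
runs. Published variant labels from other enumeration orders can be mapped
with a user-supplied alias table; nothing in the package depends on any
particular order.

The audit statistics mirror how broad-range primers are evaluated in
practice:

* **Efficiency** — fraction of reference records with at least one binding
  site under the mismatch policy, with a per-clade breakdown.
* **Redundancy** — number and percent of variants with *zero exact* matches
  anywhere in the reference library: the part of the primer mix that cannot
  bind known templates. Percent is reported at one decimal.
* **Per-variant occurrence** — for observed clone/amplicon sets, the percent
  of footprint-bearing sequences whose footprint equals each variant,
  flagged when below the *equal-distribution threshold* `100/degeneracy`
  (two decimals). These statistics use half-up rounding so printed values
  match the usual reporting convention.
* **Specificity** — fraction of a paralog decoy set (e.g. 4Fe–4S ferredoxins
  sharing the CXXCXXC motif) hit at each mismatch level.
* **Conservation profile** — per-column mean pairwise identity of an aligned
  binding region, categorized full (100%), mid (30–<100%) and low (<30%).

## Match semantics

A primer position matches a target base iff the base belongs to the
position's IUPAC set. Degenerate positions therefore never create mismatches
against concrete bases; this is equivalent to counting mismatches against
the best concrete variant, and keeps the scan single-pass. A target `N`
counts as a mismatch unless the primer position is `N` (configurable to a
wildcard). The default policy allows up to 2 mismatches but none within 5
bases of the primer 3′ end (offsets 0–4 from the terminal base), reflecting
the disproportionate effect of 3′-proximal mismatches on extension. For
reverse-orientation matching the primer is reverse complemented and the
protected window tracks the primer's 3′ terminus, which is the *left* end of
the footprint on the sense strand.

Coordinates are 1-based inclusive on the sense strand, the R/Bioconductor
(IRanges) convention.

## Melting temperatures

`melting_range()` evaluates every variant under a two-state
nearest-neighbor model using the unified DNA duplex parameter set
(SantaLucia 1998), terminal initiation corrections, an entropic salt
correction `0.368·(L−1)·ln[Na+]`, and
`Tm = ΔH / (ΔS + R ln(C_T/4)) − 273.15` for non-self-complementary oligos.
Defaults are 50 mM Na⁺ and 250 nM total oligo. Published annealing ranges
for these primers were produced by an unstated model, so they are treated as
context, not as reference values for this implementation.

# Reference packages

A reference package bundles everything classification needs: region-trimmed
nucleotide and peptide alignments, a profile model, a rooted tree with
branch lengths in substitutions/site, a 7-rank taxonomy
(`domain`…`species`, missing ranks as empty strings, skipped in LCA
computations), and outgroup flags. Packages are saved as a plain-text
directory (JSON manifest, FASTA alignments, newick, CSV, JSON profile) and
validated on load: leaves, alignment rows and taxonomy rows must coincide.

* **Region specs** are anchored intervals on one record's ungapped
  coordinates; `trim_to_region()` keeps exactly the alignment columns
  holding those anchor positions. Region labels such as "201" and "654" are
  names, not length assertions — the printed coordinates for the long
  region (268–955, a 688 nt span; the corresponding deposited genome span
  is 687 nt) are mutually inconsistent with its label, so the anchor
  interval is authoritative and the label is treated as an identifier.
* **Profile model.** Match columns (<50% gaps) store pseudocounted residue
  frequencies (Dirichlet pseudocount 0.5, shared background from the
  alignment composition); a query scores the summed per-column log₂ odds
  and the E-value-like inclusion statistic is `L·2^(−score)`. Training
  peptides score many orders of magnitude below the default inclusion
  threshold of 1e-7 while residue-shuffled peptides essentially never pass,
  which is the discrimination the threshold is asked to provide.
* **Trees.** Externally inferred maximum-likelihood newick trees are the
  primary route; a neighbor-joining builder over peptide distances exists so
  packages can be assembled without external tools. Trees are rooted on the
  flagged outgroup (non-methylator carbon monoxide dehydrogenase paralogs in
  the *hgcA* use case); if the outgroup set is not monophyletic in the
  unrooted tree the root falls back to its first member, and midpoint
  rooting is used when no outgroup exists. Negative NJ branch lengths are
  clamped to zero.
* **Identity collapse.** `collapse_by_identity()` complete-linkage clusters
  the non-outgroup aligned peptides at a cutoff (0.90/0.80 are the
  conventional choices), keeps the lexicographically smallest id per
  cluster and reports node counts before/after.

# Amplicon pipeline

`run_pipeline()` composes trimming, dereplication, optional chimera
filtering, greedy clustering and read mapping; all stages log counts.

* **Trimming** strips a configured 5′ adaptor (exact prefix) and the forward
  primer footprint (IUPAC match with ≤2 mismatches at the read start), then
  truncates to the target length (default 201 nt). Shorter reads are
  discarded, never padded. Optional quality truncation is a sliding-window
  mean (width 4) cut at the first failing window.
* **Dereplication** groups identical sequences; groups below
  `min_abundance = 2` (singletons) are dropped, since singletons inflate
  richness through sequencing error.
* **Identity** is defined as matches divided by global-alignment columns
  with end gaps penalized (Needleman–Wunsch via Biostrings; +5/−4 with gap
  open 10/extend 4 for nucleotides, BLOSUM62 with 10/1 for peptides). This
  explicit definition replaces word-filter heuristics of the common
  clustering tools so results are reproducible without them.
* **Greedy clustering** processes uniques in (abundance desc, length desc,
  sequence asc) order; a sequence joins the *first* centroid at ≥ the cutoff
  (default 0.90), else founds a new one. By construction members are ≥ the
  cutoff to their centroid and centroids are pairwise below it. Clustering
  can run in nucleotide or frame-0-translated peptide space; together with
  the chimera toggle this reproduces the four method variants commonly
  compared for functional-gene OTUs.
* **Chimera model** is a simplified two-parent single-crossover test: a
  query is flagged iff some parent-prefix/parent-suffix concatenation beats
  the best single parent's identity by ≥ `min_divergence` (0.02) and reaches
  `model_min` (0.98) identity. De novo mode restricts parents to uniques at
  least `skew = 2` times the query's abundance. All thresholds are exposed;
  they are conservative defaults, not claimed equivalents of any published
  tool's settings.
* **Mapping** assigns each read to the highest-identity centroid at ≥ the
  cutoff (ties to the earliest centroid); unassigned reads are counted per
  sample, so mapped + unmapped always equals the input.

# Classification

Per query: translation filter → profile filter → placement → LCA call.

* **Translation** assumes frame 0 and requires the first codon to be a
  table-11 initiator (ATG/GTG/TTG, translated as M); any in-frame stop
  rejects the read. The initiator set is a configuration because "first base
  is the start codon" does not by itself enumerate the alternative starts.
* **Placement** is distance-based: the query peptide is compared to every
  leaf's reference peptide by global alignment, placements within
  `score_band = 3` residue differences of the best are retained, and
  like-weight ratios are `exp(−λ·extra_differences)` normalized over the
  retained set (λ = 2). This is an explicit approximation of
  posterior-style placement weights, not a reimplementation of Bayesian
  placement machinery; the "90% cutoff" of the workflow is realized as a
  cutoff on these normalized weights.
* **LCA calls** drop placements whose *attachment* edge is ≥
  `max_branch_length = 1` substitutions/site (pendant-style distances are
  reported separately), accumulate weight along each placement leaf's
  lineage, and call the deepest rank whose best prefix reaches the
  `posterior_cutoff = 0.90`. Calls landing entirely inside the outgroup
  lineage are reported as `paralog` rather than silently dropped; failed
  translations and profile rejections are statuses, never batch errors.

Raising the cutoff can only shallow a call, and lowering the branch-length
ceiling can only unclassify — both monotonicities are tested.

# Community statistics

* **Rank aggregation** truncates lineages at the requested rank, tracks
  unclassified mass explicitly, and normalizes per sample.
* **Rarefaction** uses the analytic hypergeometric expectation
  `E[S_d] = Σ_i (1 − C(N−n_i, d)/C(N, d))` (via `vegan::rarefy`), with a
  seeded resampling mode that converges to it.
* **Sequencing error rate** aligns each read to its best-identity mock
  reference; errors are mismatches plus indels over aligned read bases,
  reported as a percent — the standard mock-community error statistic.
* **Weighted UniFrac** is computed directly from its edge sum
  `Σ_e b_e·|A_e − B_e|`, with the normalized variant (divide by
  `Σ_e b_e·(A_e + B_e)`) as the default since figures in this literature
  rarely state which was used. Community mass is anchored on the reference
  tree's leaves named by classification; a placement-edge mode is not
  provided because classified-taxon anchoring is the reproducible reading
  of "computed from the taxonomic classifications".
* **PCoA** is classical scaling (double-centering + eigendecomposition);
  negative eigenvalues are reported and their axes excluded, with no
  Cailliez correction by default.

# Synthetic data: what it emulates, and what it does not

The generators make every stage testable offline.

`make_reference_library()` diverges a random root gene into clades (default
6 clades × 4 taxa; 0.15 between-clade and 0.03 within-clade per-site
divergence — values that put different clades well below and same-clade
records well above a 90% identity cutoff over the 201 nt region, the regime
the clustering conventions assume). Every record carries planted forward and
reverse footprints drawn from configurable variant-usage distributions, an
open-reading-frame region (forced start codon, stops broken), and a layout
giving the conventional ~950 nt product. Region peptides are forced to
differ by ≥3 residues between records, emulating a curated, dereplicated
reference library; this is what makes leaf-level self-placement a
well-posed check. `make_paralog_library()` plants degraded reverse-primer
sites — by default 3 mismatches inside the protected 3′ window (never
amplifiable), with a configurable near-miss fraction carrying exactly 2
mismatches outside it.

`simulate_amplicon_run()` draws templates by largest-remainder
apportionment (realized counts match the composition exactly), prefixes the
5′ adaptor, applies i.i.d. substitutions (and optional indels) and forms
two-parent crossover chimeras with breakpoints in the interior of the
analyzed region, so planted chimeras remain chimeric in the trimmed data
the detector sees. The mock presets encode the printed three-member
compositions 41/50/9 and 59/7/35; the second sums to 101% as printed and is
normalized to proportions at the printed ratios.

Deliberately **not** emulated: PCR-cycle amplification and extraction bias
(the dominant real-world effect on mock recoveries), instrument quality
profiles (qualities are constant), adaptor-internal errors, and length
variation. Passing tests on this generator therefore demonstrate the
correctness of the algorithms under controlled conditions, not robustness
to every artifact of real libraries.

# Problem sizes and determinism

Everything is deterministic given a seed, which is recorded in generator
configs and package manifests. The test suite exercises: 1,000 random
in-silico PCR instances against a brute-force all-variant oracle (a few at
3–5 kb, the rest smaller); two 2,000-read error-free mock runs recovered
exactly at OTU level and within 2 percentage points at phylum level after
classification; a 10,000-read run at 2% planted substitution error
recovered within ±0.2 points; 1,000 reads with 10% planted chimeras from
~20%-divergent parents (sensitivity ≥0.9 at FPR ≤0.05); and closed-form
UniFrac/PCoA checks. These sizes were chosen as the smallest that make the
statistical checks stable.

# Known limitations

* Placement is an approximation; likelihood-based placement tools remain
  preferable when available, and packages accept their trees directly.
* The profile model is a position-specific scoring model, not a full hidden
  Markov model: it has no insert/delete states, so queries are compared
  ungapped against match columns (with a best-offset scan for length
  mismatches).
* Frame-0 translation assumes reads begin exactly at the start codon, as
  the trimming convention guarantees for this amplicon design; frame
  recovery for arbitrary fragments is out of scope.
* Greedy clustering is order-dependent by design (the field's convention);
  the deterministic tie-break makes it reproducible but not
  order-invariant.
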