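# IUPAC ambiguity-code algebra for degenerate PCR primers.

#' IUPAC nucleotide ambiguity codes
#'
#' Named list mapping each IUPAC DNA code to the sorted set of concrete bases
#' it stands for. DNA only; `U` is not a member.
#'
#' @return Named list of character vectors.
#' @export
iupac_sets <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
}

# complement map at the ambiguity-code level (S, W, N self-complementary)
.IUPAC_FROM <- "ACGTRYSWKMBDHVN"
.IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Validate an IUPAC primer string
#'
#' Uppercases the input and checks every character against the IUPAC DNA
#' alphabet. `U` is rejected (DNA only), with the offending position named.
#'
#' @param sequence Character scalar, written 5'->3'.
#' @return The validated, uppercased sequence.
#' @keywords internal
check_iupac <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string")
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("sequence must have length >= 1")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(iupac_sets()))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC character '%s' at position %d%s",
                 chars[bad[1]], bad[1],
                 if (chars[bad[1]] == "U") " (DNA only: U is not accepted)" else ""))
  }
  sequence
}

#' Construct a degenerate primer
#'
#' A degenerate primer is an IUPAC-encoded oligonucleotide written 5'->3'
#' representing a mixture of concrete oligo variants.
#'
#' @param name Short identifier (used as the variant id prefix).
#' @param sequence IUPAC nucleotide string, 5'->3'. Lowercase is uppercased;
#'   `U` is rejected.
#' @return An object of class `degenerate_primer` with fields `name` and
#'   `sequence`.
#' @examples
#' degenerate_primer("uni-32R", "CAGGCNCCGCAYTCSATRCA")
#' @export
degenerate_primer <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, sequence = check_iupac(sequence)),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s  5'-%s-3'  (degeneracy %d)\n",
              x$name, x$sequence, degeneracy(x)))
  invisible(x)
}

.primer_seq <- function(x) {
  if (inherits(x, "degenerate_primer")) x$sequence else check_iupac(x)
}

.primer_name <- function(x) {
  if (inherits(x, "degenerate_primer")) x$name else "primer"
}

#' Degeneracy of a primer
#'
#' The number of concrete oligonucleotide variants encoded by an IUPAC
#' primer: the product over positions of each ambiguity code's base-set
#' cardinality.
#'
#' @param primer A `degenerate_primer` or IUPAC string.
#' @return Positive integer.
#' @examples
#' degeneracy("CABGCNCCRCAYTCCATRCA")  # 96
#' degeneracy("ACGT")                  # 1
#' @export
degeneracy <- function(primer) {
  chars <- strsplit(.primer_seq(primer), "", fixed = TRUE)[[1]]
  prod(lengths(iupac_sets()[chars]))
}

#' Enumerate the concrete variants of a degenerate primer
#'
#' Enumeration is deterministic: per-position alternatives are ordered
#' A < C < G < T and the rightmost (3'-most) position varies fastest.
#' Variant ids are `"<name>-<zero-padded index>"` assigned in that order.
#'
#' @inheritParams degeneracy
#' @return A data.frame with columns `parent`, `index`, `id`, `sequence`.
#' @examples
#' expand_primer(degenerate_primer("p", "AR"))
#' @export
expand_primer <- function(primer) {
  seq <- .primer_seq(primer)
  name <- .primer_name(primer)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sets <- iupac_sets()[chars]
  # expand.grid varies its first argument fastest, so feed positions reversed
  grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  seqs <- do.call(paste0, rev(grid))
  n <- length(seqs)
  width <- max(2L, nchar(as.character(n)))
  data.frame(
    parent = name,
    index = seq_len(n),
    id = sprintf("%s-%0*d", name, width, seq_len(n)),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

#' Reverse complement of an IUPAC string
#'
#' Code-level complementation (A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H;
#' S, W and N are self-complementary), then reversal.
#'
#' @param seq IUPAC nucleotide string.
#' @return IUPAC string of the same length.
#' @examples
#' reverse_complement("CAGGCNCCGCAYTCSATRCA")
#' @export
reverse_complement <- function(seq) {
  seq <- check_iupac(seq)
  comp <- chartr(.IUPAC_FROM, .IUPAC_TO, seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Thermodynamic parameters for melting-temperature estimation
#'
#' Nearest-neighbor duplex parameters (unified set, SantaLucia 1998):
#' per-stack enthalpies (kcal/mol) and entropies (cal/(mol K)), terminal
#' initiation corrections, an entropic monovalent-salt correction of
#' `0.368 (L-1) ln[Na+]`, and the two-state Tm formula
#' `Tm = dH / (dS + R ln(C_T/4))` for non-self-complementary oligos.
#'
#' @param Na Monovalent cation concentration, mol/L. Default 0.05.
#' @param oligo_conc Total oligo concentration, mol/L. Default 2.5e-7 (250 nM).
#' @return A list with class `tm_params`.
#' @export
tm_params <- function(Na = 0.05, oligo_conc = 2.5e-7) {
  stopifnot(Na > 0, oligo_conc > 0)
  dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
          CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
          CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
          CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
          CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
          CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  structure(list(Na = Na, oligo_conc = oligo_conc, dH = dH, dS = dS,
                 init_GC = c(dH = 0.1, dS = -2.8),
                 init_AT = c(dH = 2.3, dS = 4.1)),
            class = "tm_params")
}

# two-state nearest-neighbor Tm (degrees C) for one concrete oligo
.tm_nn <- function(seq, params) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  stacks <- paste0(chars[-L], chars[-1])
  dH <- sum(params$dH[stacks])
  dS <- sum(params$dS[stacks])
  for (end in chars[c(1L, L)]) {
    init <- if (end %in% c("G", "C")) params$init_GC else params$init_AT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  dS <- dS + 0.368 * (L - 1) * log(params$Na)
  dH * 1000 / (dS + 1.987 * log(params$oligo_conc / 4)) - 273.15
}

#' Melting-temperature range of a degenerate primer
#'
#' Computes a nearest-neighbor melting temperature for every concrete
#' variant of the primer and reports the min/max over variants.
#'
#' @inheritParams degeneracy
#' @param params A [tm_params()] object.
#' @return List with `t_min`, `t_max` (degrees C) and the per-variant
#'   data.frame `per_variant` (columns `id`, `sequence`, `tm`).
#' @export
melting_range <- function(primer, params = tm_params()) {
  seq <- .primer_seq(primer)
  if (nchar(seq) < 8L)
    stop(sprintf("unsupported length: primer has %d nt, nearest-neighbor model requires >= 8",
                 nchar(seq)))
  variants <- expand_primer(primer)
  variants$tm <- vapply(variants$sequence, .tm_nn, numeric(1), params = params)
  list(t_min = min(variants$tm), t_max = max(variants$tm),
       per_variant = variants[, c("id", "sequence", "tm")])
}

#' Read primers from FASTA or a key=value config file
#'
#' FASTA headers become primer names. Config files hold one
#' `name = IUPAC_SEQUENCE` pair per line (`#` comments allowed).
#'
#' @param path File path.
#' @return Named list of `degenerate_primer` objects.
#' @export
read_primers <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(startsWith(trimws(lines), ">"))) {
    set <- Biostrings::readBStringSet(path)
    prs <- mapply(degenerate_primer, names(set), as.character(set),
                  SIMPLIFY = FALSE)
  } else {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    if (any(lengths(kv) != 2L)) stop("config lines must be 'name = sequence'")
    prs <- lapply(kv, function(p) degenerate_primer(trimws(p[1]), trimws(p[2])))
    names(prs) <- vapply(prs, `[[`, "", "name")
  }
  prs
}

#' Write the expanded variants of a primer as FASTA
#'
#' @inheritParams degeneracy
#' @param path Output FASTA path.
#' @return Invisibly, the variant data.frame.
#' @export
write_variants <- function(primer, path) {
  v <- expand_primer(primer)
  set <- Biostrings::DNAStringSet(v$sequence)
  names(set) <- v$id
  Biostrings::writeXStringSet(set, path)
  invisible(v)
}
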