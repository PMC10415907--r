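# Global pairwise alignment with affine gaps, plus the identity measures
# used by parent assignment, chimera scanning and conservation reporting.
#
# Gap convention: a gap of length L costs gap_open + (L - 1) * gap_extend,
# with gap_open <= gap_extend <= 0 (the first gapped position carries the
# opening penalty).  The dynamic programming itself is delegated to
# Biostrings::pairwiseAlignment, whose internal convention
# (opening + L * extension) is remapped exactly.

#' Alignment parameters
#'
#' Defaults follow common conventions: for DNA match = 2, mismatch = -3,
#' gap open = -5, gap extend = -2; for protein the BLOSUM62 matrix with
#' gap open = -10, gap extend = -1.
#'
#' @param alphabet `"dna"` or `"protein"`.
#' @param match,mismatch DNA match/mismatch scores (ignored for protein).
#' @param gap_open,gap_extend Gap penalties, `gap_open <= gap_extend <= 0`.
#'   A gap of length L costs `gap_open + (L - 1) * gap_extend`.
#' @param submat Name of a protein substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`); ignored for DNA.
#' @return A list of class `align_params`.
#' @export
align_params <- function(alphabet = c("dna", "protein"), match = 2,
                         mismatch = -3, gap_open = NULL, gap_extend = NULL,
                         submat = "BLOSUM62") {
  alphabet <- match.arg(alphabet)
  if (is.null(gap_open)) gap_open <- if (alphabet == "dna") -5 else -10
  if (is.null(gap_extend)) gap_extend <- if (alphabet == "dna") -2 else -1
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("invalid gap penalties: need gap_open <= gap_extend <= 0")
  structure(list(alphabet = alphabet, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 submat = submat),
            class = "align_params")
}

# Substitution matrix for the given params.  For DNA, ambiguity N scores as
# a mismatch against everything (including N), so runs of Ns never inflate
# identity.
substitution_matrix <- function(params) {
  if (params$alphabet == "dna") {
    m <- matrix(params$mismatch, 5L, 5L,
                dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
    diag(m) <- params$match
    m["N", ] <- params$mismatch
    m[, "N"] <- params$mismatch
    m
  } else {
    e <- new.env()
    utils::data(list = params$submat, package = "Biostrings", envir = e)
    get(params$submat, envir = e)
  }
}

# Map the package gap convention onto Biostrings' (opening + L * extension).
bs_gap <- function(params) {
  list(opening = -(params$gap_open - params$gap_extend),
       extension = -params$gap_extend)
}

#' Global (Needleman-Wunsch) pairwise alignment
#'
#' @param a,b Sequences: either bare strings or one-row record data.frames
#'   (see [read_fasta()]).  Must be non-empty and share an alphabet.
#' @param params An [align_params()] object; defaults to DNA parameters when
#'   both inputs look like DNA, protein parameters otherwise.
#' @return A list of class `pairwise_alignment` with elements `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score` and `identity`
#'   (aligned-columns mode).
#' @export
global_align <- function(a, b, params = NULL) {
  sa <- as_residues(a); sb <- as_residues(b)
  if (nchar(sa) == 0L || nchar(sb) == 0L)
    stop("precondition violation: sequences must be non-empty")
  ab_a <- infer_alphabet(sa); ab_b <- infer_alphabet(sb)
  if (is.null(params))
    params <- align_params(if (ab_a == "dna" && ab_b == "dna") "dna" else "protein")
  if (params$alphabet == "dna" && (ab_a != "dna" || ab_b != "dna"))
    stop("alphabet error: non-DNA residues with DNA alignment parameters")
  mat <- substitution_matrix(params)
  g <- bs_gap(params)
  aln <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global", substitutionMatrix = mat,
    gapOpening = g$opening, gapExtension = g$extension)
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  out <- list(aligned_a = ga, aligned_b = gb,
              score = Biostrings::score(aln), identity = NA_real_,
              params = params)
  class(out) <- "pairwise_alignment"
  out$identity <- percent_identity(out, "aligned_columns")
  out
}

#' Percent identity of a pairwise alignment
#'
#' @param aln A `pairwise_alignment` (or any list with `aligned_a` /
#'   `aligned_b` equal-length gapped strings).
#' @param mode `"aligned_columns"`: matches / columns with residues in both
#'   rows; `"shorter_seq"`: matches / length of the shorter (ungapped)
#'   sequence.
#' @return A fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln, mode = c("aligned_columns", "shorter_seq")) {
  mode <- match.arg(mode)
  ca <- chars(aln$aligned_a); cb <- chars(aln$aligned_b)
  stopifnot(length(ca) == length(cb))
  both <- ca != "-" & cb != "-"
  matches <- sum(both & ca == cb)
  denom <- if (mode == "aligned_columns") sum(both)
           else min(sum(ca != "-"), sum(cb != "-"))
  if (denom == 0L)
    stop("undefined identity: zero comparable positions")
  matches / denom
}

# Glocal alignment: the full `long` sequence is scanned for the best fit of
# the complete `short` sequence (global in `short`, local in `long`).  Used
# by intron-loss assessment and parent assignment, where a spliced mRNA is
# matched inside a genomic window.
fit_align <- function(short, long, params = NULL) {
  ss <- as_residues(short); sl <- as_residues(long)
  if (nchar(ss) == 0L || nchar(sl) == 0L)
    stop("precondition violation: sequences must be non-empty")
  if (is.null(params)) {
    ab <- if (infer_alphabet(ss) == "dna" && infer_alphabet(sl) == "dna")
      "dna" else "protein"
    params <- align_params(ab)
  }
  mat <- substitution_matrix(params)
  g <- bs_gap(params)
  aln <- Biostrings::pairwiseAlignment(
    ss, sl, type = "global-local", substitutionMatrix = mat,
    gapOpening = g$opening, gapExtension = g$extension)
  out <- list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
              aligned_b = as.character(Biostrings::alignedSubject(aln)),
              score = Biostrings::score(aln), params = params)
  class(out) <- "pairwise_alignment"
  out
}
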