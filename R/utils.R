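#' @keywords internal
"_PACKAGE"

# Alphabet definitions.  Gap '-' is legal only in aligned records; ambiguity
# characters (N for DNA, X for protein) are legal residues but are treated as
# missing data by the conservation and distance code.
DNA_LETTERS <- c("A", "C", "G", "T")
DNA_ALPHABET <- c(DNA_LETTERS, "N")
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA_LETTERS, "X")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a DNA string
#'
#' @param x A single DNA string (characters ACGTN, case-insensitive).
#' @return The reverse complement, uppercased.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(toupper(x), "", fixed = TRUE)[[1]]), collapse = ""))
}

# Split a string into a character vector (one element per residue).
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Infer alphabet of an uppercased residue string: "dna" when every character
# is ACGTN or '-', otherwise "protein".
infer_alphabet <- function(residues) {
  cs <- unique(chars(residues))
  if (all(cs %in% c(DNA_ALPHABET, "-"))) "dna" else "protein"
}

# Validate residues against a declared alphabet; errors name the offending
# record and 1-based position.
check_alphabet <- function(residues, alphabet, id = "<unnamed>",
                           allow_gap = FALSE) {
  legal <- switch(alphabet,
                  dna = DNA_ALPHABET,
                  protein = c(AA_ALPHABET, "*"),
                  stop("unknown alphabet: ", alphabet))
  if (allow_gap) legal <- c(legal, "-")
  cs <- chars(residues)
  bad <- which(!(cs %in% legal))
  if (length(bad) > 0L) {
    stop(sprintf("alphabet error: record '%s' has illegal %s residue '%s' at position %d",
                 id, alphabet, cs[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

# Codon table is only needed for stop detection; translation for reports is a
# plain lookup.
GENETIC_CODE_VEC <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  codons <- sort(codons)
  Biostrings::GENETIC_CODE[codons]
})

# Translate an in-frame DNA string codon by codon; incomplete trailing codon
# is dropped.  Stops are '*'; codons containing N become 'X'.
translate_cds <- function(body) {
  n <- nchar(body) %/% 3L
  if (n == 0L) return("")
  codons <- substring(body, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  aa <- GENETIC_CODE_VEC[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# A single sequence record as a one-row data.frame; several functions accept
# either a record data.frame or a bare string.
as_residues <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("residues" %in% names(x), nrow(x) == 1L)
    x$residues
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    toupper(x)
  }
}

record_id <- function(x, default = "<seq>") {
  if (is.data.frame(x) && "id" %in% names(x)) x$id else default
}
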