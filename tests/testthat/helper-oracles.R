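# Independent oracles used across the suite.  These deliberately avoid the
# package's own algorithmic paths: the alignment oracle enumerates every
# monotone alignment, the column oracles are plain loops.

# Exhaustive global-alignment score under affine gaps: a gap of length L
# costs gap_open + (L - 1) * gap_extend.  Feasible for lengths <= 6.
brute_align_score <- function(a, b, match = 2, mismatch = -3,
                              gap_open = -5, gap_extend = -2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > na && j > nb) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, sc + if (ca[i] == cb[j]) match else mismatch, "M")
    if (i <= na)
      rec(i + 1L, j, sc + if (last == "A") gap_extend else gap_open, "A")
    if (j <= nb)
      rec(i, j + 1L, sc + if (last == "B") gap_extend else gap_open, "B")
  }
  rec(1L, 1L, 0, "M")
  best
}

# Plain column scan for fully conserved columns (no gaps, all identical).
brute_conserved <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (!any(col == "-") && all(col == col[1])) n <- n + 1L
  }
  list(n_conserved = n, n_columns = ncol(m))
}

# Plain per-column coverage filter (>= min_cov unambiguous residues).
brute_filter_keep <- function(seqs, min_cov, bad = c("-", "?", "N")) {
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    keep[j] <- mean(!(m[, j] %in% bad)) >= min_cov
  }
  keep
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
rand_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

# Point-substitute a string at the given per-site rate.
perturb_seq <- function(s, rate, letters = AA20) {
  cs <- strsplit(s, "")[[1]]
  idx <- which(stats::runif(length(cs)) < rate)
  for (i in idx) cs[i] <- sample(setdiff(letters, cs[i]), 1L)
  paste(cs, collapse = "")
}

# A random unrooted-able tree with branch lengths, via ape.
rand_tree <- function(n, min_bl = 0.05, max_bl = 0.2) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

# Verify a simulated insertion's truth record against the emitted genome by
# direct string inspection of the strand-normalized window.
verify_insertion_truth <- function(sim, i, up = 200L, down = 400L) {
  tr <- sim$truth$insertions[[i]]
  locus <- sim$loci[sim$loci$locus_id == tr$locus_id, , drop = FALSE]
  w <- extract_window(sim$genome, locus, up, down)
  sig_ok <- substr(w$downstream, tr$signal_pos + 1L, tr$signal_pos + 6L) ==
    "AATAAA"
  tail_seq <- substr(w$downstream, tr$tail_start + 1L,
                     tr$tail_start + tr$tail_len)
  tsd_dn <- substr(w$downstream, tr$tail_start + tr$tail_len + 1L,
                   tr$tail_start + tr$tail_len + tr$tsd_len)
  up_off <- nchar(w$upstream) - tr$utr5_rem_len - tr$tsd_len
  tsd_up <- substr(w$upstream, up_off + 1L, up_off + tr$tsd_len)
  body_ok <- !tr$has_canonical_start || startsWith(w$body, "ATG")
  list(window = w, truth = tr,
       signal_ok = sig_ok,
       tail_ok = length(tr$planted_mutations) > 0 ||
         tail_seq == strrep("A", tr$tail_len),
       tsd_ok = tsd_dn == tr$tsd_sequence && tsd_up == tr$tsd_sequence,
       body_ok = body_ok)
}
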