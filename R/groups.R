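# IR-IFITM group machinery: conservation statistics, numeric sequence-logo
# matrices, termini-based position-weight-matrix (PWM) profiles, sequence
# classification into groups, and consensus-difference reporting.
#
# The group vocabulary follows the six-group nomenclature for primate
# immunity-related IFITMs (IR-pIFITM1/2/3, IR-pIFITMnwm, IR-pIFITMowm,
# IR-pIFITMpro), but profiles are user-defined: any label works.

IR_GROUP_LABELS <- c("IR-pIFITM1", "IR-pIFITM2", "IR-pIFITM3",
                     "IR-pIFITMnwm", "IR-pIFITMowm", "IR-pIFITMpro")

#' Build an MSA container
#'
#' @param records Data.frame of aligned records (equal-length gapped
#'   residues; see [read_fasta()] with `aligned = TRUE`).
#' @param alphabet `"dna"`, `"protein"` or `"auto"`.
#' @return A list of class `msa` with `ids`, `seqs`, `alphabet`.
#' @export
as_msa <- function(records, alphabet = "auto") {
  stopifnot(is.data.frame(records), nrow(records) >= 2L)
  lens <- nchar(records$residues)
  if (length(unique(lens)) != 1L)
    stop("alignment error: records have unequal lengths")
  if (alphabet == "auto")
    alphabet <- infer_alphabet(paste(records$residues, collapse = ""))
  structure(list(ids = records$id, seqs = toupper(records$residues),
                 alphabet = alphabet),
            class = "msa")
}

# Character matrix view of an MSA (rows = sequences).
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$seqs, "", fixed = TRUE))
}

msa_alphabet_letters <- function(msa) {
  if (msa$alphabet == "dna") DNA_LETTERS else AA_LETTERS
}

#' Fraction of fully conserved alignment columns
#'
#' A column counts as conserved iff all rows carry the identical residue
#' and no row has a gap (the strictest reading of "100% conserved").
#'
#' @param msa An `msa`.
#' @return A list with `n_conserved`, `n_columns`, `fraction`.
#' @export
conserved_fraction <- function(msa) {
  m <- msa_matrix(msa)
  if (ncol(m) == 0L) stop("zero-length alignment")
  cons <- apply(m, 2L, function(col) {
    !any(col == "-") && length(unique(col)) == 1L
  })
  list(n_conserved = sum(cons), n_columns = ncol(m),
       fraction = sum(cons) / ncol(m))
}

#' Numeric sequence-logo matrix
#'
#' Probability mode gives per-column residue frequencies with gaps (and
#' ambiguity characters) excluded from the denominator.  Information mode
#' additionally reports the per-column information content
#' `IC = log2(A) + sum(p * log2(p))` with `A` the alphabet size and no
#' small-sample correction.  All-gap columns are flagged and get `IC = 0`.
#'
#' @param msa An `msa`.
#' @param mode `"probability"` or `"information"`.
#' @return A list of class `logo_matrix`: `prob` (alphabet x columns),
#'   `ic` (when requested), `flagged_columns`.
#' @export
logo_matrix <- function(msa, mode = c("probability", "information")) {
  mode <- match.arg(mode)
  m <- msa_matrix(msa)
  if (ncol(m) == 0L) stop("zero-length alignment")
  letters <- msa_alphabet_letters(msa)
  A <- length(letters)
  prob <- matrix(NA_real_, A, ncol(m), dimnames = list(letters, NULL))
  flagged <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% letters]
    if (length(col) == 0L) { flagged[j] <- TRUE; next }
    prob[, j] <- tabulate(match(col, letters), A) / length(col)
  }
  out <- list(prob = prob, flagged_columns = which(flagged))
  if (mode == "information") {
    ic <- vapply(seq_len(ncol(m)), function(j) {
      p <- prob[, j]
      if (any(is.na(p))) return(0)
      p <- p[p > 0]
      log2(A) + sum(p * log2(p))
    }, 0)
    out$ic <- ic
  }
  structure(out, class = "logo_matrix")
}

# Majority-rule consensus of an MSA: per column the most frequent residue
# (gaps and ambiguity excluded; ties broken alphabetically).  Columns with
# no residue at all are dropped.
msa_consensus <- function(msa) {
  m <- msa_matrix(msa)
  letters <- msa_alphabet_letters(msa)
  cons <- apply(m, 2L, function(col) {
    col <- col[col %in% letters]
    if (length(col) == 0L) return(NA_character_)
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[tab == max(tab)][1]
  })
  paste(cons[!is.na(cons)], collapse = "")
}

#' Build a terminus-signature group profile
#'
#' PWMs are estimated from the designated N- and C-terminal column blocks
#' with additive pseudocounts; length ranges come from the ungapped member
#' lengths inside each block.  The central domain (typically the conserved
#' CD225 domain) is deliberately not part of the profile.
#'
#' @param msa Group member `msa` (protein).
#' @param group_label Profile label.
#' @param n_term_cols,c_term_cols Integer vectors `c(first, last)` of
#'   1-based alignment columns for the two terminal blocks (must not
#'   overlap).
#' @param pseudocount Additive pseudocount per residue.
#' @return A list of class `group_profile`.
#' @export
build_group_profile <- function(msa, group_label, n_term_cols, c_term_cols,
                                pseudocount = 0.5) {
  m <- msa_matrix(msa)
  nc <- ncol(m)
  stopifnot(length(n_term_cols) == 2L, length(c_term_cols) == 2L)
  if (n_term_cols[1] > n_term_cols[2] || c_term_cols[1] > c_term_cols[2] ||
      n_term_cols[1] < 1L || c_term_cols[2] > nc)
    stop("argument error: block intervals outside alignment")
  if (n_term_cols[2] >= c_term_cols[1])
    stop("argument error: N- and C-terminal blocks overlap")
  letters <- msa_alphabet_letters(msa)
  A <- length(letters)
  pwm_block <- function(cols) {
    block <- m[, seq.int(cols[1], cols[2]), drop = FALSE]
    pwm <- apply(block, 2L, function(col) {
      counts <- tabulate(match(col[col %in% letters], letters), A)
      (counts + pseudocount) / (sum(counts) + A * pseudocount)
    })
    rownames(pwm) <- letters
    pwm
  }
  len_range <- function(cols) {
    block <- m[, seq.int(cols[1], cols[2]), drop = FALSE]
    lens <- apply(block, 1L, function(row) sum(row != "-"))
    range(lens)
  }
  structure(list(group_label = group_label,
                 n_term_pwm = pwm_block(n_term_cols),
                 c_term_pwm = pwm_block(c_term_cols),
                 n_term_cols = n_term_cols, c_term_cols = c_term_cols,
                 n_term_len_range = len_range(n_term_cols),
                 c_term_len_range = len_range(c_term_cols),
                 pseudocount = pseudocount,
                 floor_prob = pseudocount /
                   (length(msa$ids) + A * pseudocount),
                 consensus = msa_consensus(msa),
                 n_members = length(msa$ids)),
            class = "group_profile")
}

# Score one profile against an ungapped query: align the query to the
# profile consensus, then sum log PWM probabilities over the terminal-block
# columns.  Gaps and residues outside the PWM alphabet score at the
# pseudocount floor.
score_profile <- function(seq, profile, params) {
  aln <- global_align(seq, profile$consensus, params)
  cq <- chars(aln$aligned_a); cc <- chars(aln$aligned_b)
  cons_pos <- cumsum(cc != "-")
  score_block <- function(cols, pwm) {
    total <- 0
    seg_res <- 0L
    for (p in seq.int(cols[1], cols[2])) {
      k <- p - cols[1] + 1L
      col_idx <- which(cc != "-" & cons_pos == p)
      r <- if (length(col_idx) == 1L) cq[col_idx] else "-"
      pr <- if (r %in% rownames(pwm)) pwm[r, k] else profile$floor_prob
      if (r != "-") seg_res <- seg_res + 1L
      total <- total + log(pr)
    }
    list(score = total, len = seg_res)
  }
  nb <- score_block(profile$n_term_cols, profile$n_term_pwm)
  cb <- score_block(profile$c_term_cols, profile$c_term_pwm)
  list(score = nb$score + cb$score,
       n_len_ok = nb$len >= profile$n_term_len_range[1] &&
         nb$len <= profile$n_term_len_range[2],
       c_len_ok = cb$len >= profile$c_term_len_range[1] &&
         cb$len <= profile$c_term_len_range[2])
}

#' Classify a sequence against group profiles
#'
#' Scores the sequence's terminal blocks (located by global alignment to
#' each profile's consensus) under each profile's PWMs.  The winner is the
#' maximum summed log probability; exact ties are broken by lexicographic
#' group label and flagged ambiguous.  Sequences shorter than the smallest
#' combined terminal-block minimum of the profiles are `"indeterminate"`.
#'
#' @param seq Ungapped protein sequence (record or string).
#' @param profiles List of `group_profile`s (at least 2).
#' @param params Optional [align_params()] (protein defaults).
#' @return A list with `group_label`, `scores` (named), `margin`,
#'   `ambiguous`, `length_flags`.
#' @export
classify_sequence <- function(seq, profiles, params = NULL) {
  stopifnot(length(profiles) >= 2L)
  s <- as_residues(seq)
  if (grepl("-", s, fixed = TRUE))
    stop("argument error: query must be ungapped")
  if (is.null(params)) params <- align_params("protein")
  labels <- vapply(profiles, function(p) p$group_label, "")
  ord <- order(labels)
  profiles <- profiles[ord]; labels <- labels[ord]
  min_needed <- min(vapply(profiles, function(p)
    p$n_term_len_range[1] + p$c_term_len_range[1], 0))
  if (nchar(s) < min_needed)
    return(list(group_label = "indeterminate",
                scores = stats::setNames(rep(NA_real_, length(labels)), labels),
                margin = NA_real_, ambiguous = FALSE,
                length_flags = NULL))
  res <- lapply(profiles, function(p) score_profile(s, p, params))
  scores <- stats::setNames(vapply(res, function(r) r$score, 0), labels)
  best <- which.max(scores)          # leftmost max = lexicographic tie-break
  sorted <- sort(scores, decreasing = TRUE)
  margin <- if (length(sorted) >= 2L) sorted[1] - sorted[2] else NA_real_
  flags <- data.frame(group_label = labels,
                      n_len_ok = vapply(res, function(r) r$n_len_ok, TRUE),
                      c_len_ok = vapply(res, function(r) r$c_len_ok, TRUE),
                      stringsAsFactors = FALSE)
  list(group_label = labels[best], scores = scores,
       margin = as.numeric(margin),
       ambiguous = isTRUE(margin == 0), length_flags = flags)
}

#' Substitutions of a sequence relative to a consensus
#'
#' Aligns the query to the consensus and reports one entry per aligned
#' column where the residues differ, formatted as consensus residue +
#' 1-based consensus position + query residue (e.g. `"G19R"`).
#'
#' @param seq,consensus Ungapped protein sequences (records or strings).
#' @param params Optional [align_params()].
#' @return Character vector of substitution strings (empty when identical).
#' @export
consensus_diff <- function(seq, consensus, params = NULL) {
  if (is.null(params)) params <- align_params("protein")
  aln <- global_align(seq, consensus, params)
  cq <- chars(aln$aligned_a); cc <- chars(aln$aligned_b)
  cons_pos <- cumsum(cc != "-")
  idx <- which(cq != "-" & cc != "-" & cq != cc)
  if (length(idx) == 0L) return(character(0))
  paste0(cc[idx], cons_pos[idx], cq[idx])
}
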