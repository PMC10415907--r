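# Retrogene hallmark scanner.
#
# For each candidate locus the scanner inspects a strand-normalized window:
# up to 200 bp immediately 5' of the canonical start codon, the coding body,
# and up to 400 bp immediately 3' of the canonical stop codon.  Five
# hallmark detectors (intron loss, poly-A signal, poly-A tail start,
# target-site duplications, premature stop codon) are composed into a
# retrogene / retropseudogene verdict; parental mRNAs are assigned by
# identity over CDS and UTR regions.  All offsets reported by the detectors
# are 0-based within the window part they refer to.

#' Extract a strand-normalized scan window around a locus
#'
#' On the minus strand all three parts are reverse-complemented and swapped
#' so that "upstream" always means 5' of the coding sequence.  Windows are
#' truncated without error at contig edges.
#'
#' @param genome A genome record (one-row data.frame from [read_fasta()]) or
#'   a bare DNA string.
#' @param locus One-row loci data.frame (0-based half-open coordinates).
#' @param up,down Maximum upstream / downstream window lengths (bp).
#' @return A list of class `retro_window` with elements `locus_id`,
#'   `strand`, `upstream`, `body`, `downstream`.
#' @export
extract_window <- function(genome, locus, up = 200L, down = 400L) {
  stopifnot(up >= 0L, down >= 0L, nrow(locus) == 1L)
  if (is.data.frame(genome) && nrow(genome) > 1L) {
    genome <- genome[genome$id == locus$contig, , drop = FALSE]
    if (nrow(genome) != 1L)
      stop("coordinate error: contig not found: ", locus$contig)
  }
  g <- as_residues(genome)
  n <- nchar(g)
  s <- locus$start; e <- locus$end
  if (s < 0L || e > n || s >= e)
    stop("coordinate error: locus ", locus$locus_id,
         " [", s, ",", e, ") outside contig of length ", n)
  if (locus$strand == "+") {
    upstream <- substr(g, max(0L, s - up) + 1L, s)
    body <- substr(g, s + 1L, e)
    downstream <- substr(g, e + 1L, min(n, e + down))
  } else {
    body <- revcomp(substr(g, s + 1L, e))
    upstream <- revcomp(substr(g, e + 1L, min(n, e + up)))
    downstream <- revcomp(substr(g, max(0L, s - down) + 1L, s))
  }
  structure(list(locus_id = locus$locus_id, strand = locus$strand,
                 upstream = upstream, body = body, downstream = downstream),
            class = "retro_window")
}

#' Find the poly-A signal hexamer downstream of the stop codon
#'
#' Reports the 0-based offset (within the downstream window) of the first
#' exact `AATAAA` occurrence, or `NA` when absent.  The common `ATTAAA`
#' variant can be enabled explicitly.
#'
#' @param window A `retro_window`.
#' @param allow_attaaa Also accept the ATTAAA variant (off by default).
#' @return Integer offset or `NA`.
#' @export
find_polya_signal <- function(window, allow_attaaa = FALSE) {
  d <- window$downstream
  if (nchar(d) == 0L) return(NA_integer_)
  hits <- as.integer(regexpr("AATAAA", d, fixed = TRUE))
  if (allow_attaaa) {
    alt <- as.integer(regexpr("ATTAAA", d, fixed = TRUE))
    hits <- c(hits, alt)
  }
  hits <- hits[hits > 0L]
  if (length(hits) == 0L) return(NA_integer_)
  min(hits) - 1L
}

#' Find the start of the poly-A tail
#'
#' The tail start is the first downstream position `p` that is an `A`, whose
#' next `min_run` bases are at least `purity` A, and (when a poly-A signal
#' was found) that lies within `max_gap_to_signal` bases of the signal end.
#'
#' @param window A `retro_window`.
#' @param signal_pos Offset from [find_polya_signal()], or `NA`.
#' @param min_run Minimum run length inspected (bases).  The default (12)
#'   reflects the substantial poly-A stretch LINE-1 machinery requires;
#'   random genomic runs of that length and purity are rare.
#' @param purity Minimum A fraction over the run.
#' @param max_gap_to_signal Maximum distance from the signal end (bases).
#' @return Integer 0-based offset within the downstream window, or `NA`.
#' @export
find_polya_tail <- function(window, signal_pos = NA_integer_, min_run = 12L,
                            purity = 0.8, max_gap_to_signal = 50L) {
  d <- chars(window$downstream)
  n <- length(d)
  if (n < min_run) return(NA_integer_)
  is_a <- d == "A"
  run_a <- stats::filter(as.integer(is_a), rep(1L, min_run), sides = 1)
  # run_a[i] = #A in d[(i-min_run+1)..i]; shift so counts[p] covers p..p+min_run-1
  counts <- as.integer(run_a[seq(min_run, n)])
  cand0 <- if (!is.na(signal_pos)) {
    from <- signal_pos + 6L
    seq.int(from, min(from + max_gap_to_signal, n - min_run))
  } else seq.int(0L, n - min_run)
  cand0 <- cand0[cand0 >= 0L & cand0 <= n - min_run]
  for (p in cand0) {
    if (is_a[p + 1L] && counts[p + 1L] >= purity * min_run) return(p)
  }
  NA_integer_
}

# Mismatch budget for a TSD candidate of length `len`: one allowance per
# COMPLETE 10 bp, so short repeats (< 10 bp) must match exactly -- a 6-mer
# with a free mismatch is indistinguishable from background.
tsd_budget <- function(len, max_mismatch_per_10bp) {
  as.integer((len %/% 10L) * max_mismatch_per_10bp)
}

# End of the poly-A run beginning at `tail_start` (0-based, exclusive).
# Isolated non-A bases inside the tail are skipped as long as the following
# 8 bases remain A-rich (>= 6 A), so a point mutation does not truncate the
# run; the run stops where downstream sequence stops being A-dominated.
polya_run_end <- function(d, tail_start) {
  n <- length(d)
  i <- tail_start                     # 0-based; d[i + 1] is the next base
  while (i < n) {
    if (d[i + 1L] == "A") { i <- i + 1L; next }
    ahead <- d[seq.int(i + 2L, length.out = min(8L, n - i - 1L))]
    if (length(ahead) == 8L && sum(ahead == "A") >= 6L) { i <- i + 1L; next }
    break
  }
  i
}

#' Find target-site duplications flanking a retro-insertion
#'
#' Mirrors the target-site primed reverse transcription geometry: the
#' downstream TSD copy must begin within `search_after_tail` bases after
#' the end of the poly-A run (the TSD is directly adjacent to the tail),
#' and the upstream copy must end within `upstream_search` bases of the
#' canonical start codon (it sits immediately 5' of the retro-copy's
#' 5' UTR).  Candidate repeats must match at both ends and stay within the
#' mismatch budget; they are ranked by downstream-copy proximity to the
#' tail end, then fewest mismatches, then length, then upstream-copy
#' proximity to the insertion junction.
#'
#' @param window A `retro_window`.
#' @param tail_start Tail offset from [find_polya_tail()].
#' @param min_len,max_len TSD length bounds (bp).
#' @param max_mismatch_per_10bp Mismatch allowance per complete 10 bp of
#'   repeat length (repeats under 10 bp must match exactly).
#' @param search_after_tail Search span after the poly-A run end (bp).
#' @param upstream_search The upstream copy must end within this many bases
#'   of the canonical start codon (bounds the plausible 5' UTR length).
#' @return A list of class `tsd` (`sequence`, `upstream_pos`,
#'   `downstream_pos`, `length`, `mismatches`; offsets 0-based within their
#'   window part) or `NULL` when no pair qualifies.
#' @export
find_tsd <- function(window, tail_start, min_len = 6L, max_len = 25L,
                     max_mismatch_per_10bp = 1L, search_after_tail = 10L,
                     upstream_search = 120L) {
  d <- chars(window$downstream)
  u <- chars(window$upstream)
  n <- length(d); m <- length(u)
  if (is.na(tail_start) || tail_start < 0L || tail_start >= n)
    stop("invalid tail_start: ", tail_start)
  if (m < min_len || n < min_len) return(NULL)
  tail_end <- polya_run_end(d, tail_start)
  s_last <- min(tail_end + search_after_tail, n - min_len)
  if (s_last < tail_end) return(NULL)
  # 1-based upstream start positions whose copy can still END inside the
  # allowed region near the start codon
  u_first <- max(1L, m - upstream_search - max_len + 2L)
  best <- NULL  # ranking: s asc, mm asc, len desc, u desc
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$s0 != b$s0) return(a$s0 < b$s0)
    if (a$mm != b$mm) return(a$mm < b$mm)
    if (a$len != b$len) return(a$len > b$len)
    a$u0 > b$u0
  }
  for (s0 in seq.int(tail_end, s_last)) {
    l_max <- min(max_len, n - s0)
    if (l_max < min_len) next
    ds <- d[(s0 + 1L):(s0 + l_max)]
    for (u1 in seq.int(u_first, m - min_len + 1L)) {
      l_here <- min(l_max, m - u1 + 1L)
      if (l_here < min_len) next
      us <- u[u1:(u1 + l_here - 1L)]
      mism <- cumsum(us != ds[seq_len(l_here)])
      for (len in seq.int(l_here, min_len)) {
        if (us[1] != ds[1] || us[len] != ds[len]) next   # ends must match
        mm <- mism[len]
        if (mm > tsd_budget(len, max_mismatch_per_10bp)) next
        # the upstream copy must END within upstream_search of the window end
        if (u1 + len - 1L < m - upstream_search + 1L) next
        cand <- list(len = len, mm = as.integer(mm), s0 = s0, u0 = u1 - 1L)
        if (better(cand, best)) best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(list(sequence = paste(d[(best$s0 + 1L):(best$s0 + best$len)],
                                  collapse = ""),
                 upstream_pos = best$u0, downstream_pos = best$s0,
                 length = best$len, mismatches = best$mm),
            class = "tsd")
}

#' Assess coding-sequence integrity of a retro-copy
#'
#' Translates the body in frame 0 and reports the first premature stop
#' codon (1-based codon index) and whether the CDS is complete (no premature
#' stop and the final codon is a stop).
#'
#' @param body In-frame DNA string starting with ATG (length >= 6).
#' @param expected_aa_len Expected protein length (codons before the stop),
#'   typically taken from the assigned parent; `NULL` uses the copy's own
#'   final codon as the reference.
#' @return A list with `premature_stop_codon_index` (integer or `NA`) and
#'   `full_cds` (logical).
#' @export
detect_cds_integrity <- function(body, expected_aa_len = NULL) {
  body <- toupper(body)
  if (!startsWith(body, "ATG"))
    stop("no-canonical-start error: body does not begin with ATG")
  if (nchar(body) < 6L) stop("body too short (< 6 nt)")
  aa <- translate_cds(body)
  stops <- which(chars(aa) == "*")
  n_codons <- nchar(aa)
  limit <- if (is.null(expected_aa_len)) n_codons else expected_aa_len + 1L
  premature <- NA_integer_
  if (length(stops) > 0L && stops[1] < limit) premature <- stops[1]
  full <- is.na(premature) && nchar(body) %% 3L == 0L &&
    length(stops) > 0L && stops[length(stops)] == n_codons
  list(premature_stop_codon_index = premature, full_cds = full)
}

#' Assess intron loss against an intron-bearing parent
#'
#' Fits the parent mRNA inside the genomic window and inspects every
#' exon-exon junction of the parent: intron loss (`"yes"`) requires each
#' junction to be spanned by at least `min_junction_cov` aligned bases with
#' at most `max_junction_gaps` gaps; a genomic insertion of at least
#' `min_insert` bases coinciding with a junction yields `"no"`; anything
#' else is `"unknown"`.
#'
#' @param body Body DNA of the candidate (canonical start..stop).
#' @param parent_mrna Spliced parent transcript (record or string).
#' @param parent_exon_lengths Integer vector of exon lengths summing to the
#'   mRNA length.
#' @param window Optional `retro_window`; when given, the upstream and
#'   downstream parts are included so UTR-containing exons can align.
#' @param min_junction_cov,max_junction_gaps,min_insert Rule thresholds.
#' @param params Optional [align_params()].  The default uses a mild gap
#'   extension (-0.5) so that a retained intron aligns as one long gap
#'   rather than being mismatched through -- the decisive signal here is
#'   the gap structure, not the substitution score.
#' @return One of `"yes"`, `"no"`, `"unknown"`.
#' @export
assess_intron_loss <- function(body, parent_mrna, parent_exon_lengths,
                               window = NULL, min_junction_cov = 20L,
                               max_junction_gaps = 2L, min_insert = 50L,
                               params = align_params("dna",
                                                     gap_extend = -0.5)) {
  pm <- as_residues(parent_mrna)
  if (sum(parent_exon_lengths) != nchar(pm))
    stop("annotation error: exon lengths (", sum(parent_exon_lengths),
         ") do not sum to mRNA length (", nchar(pm), ")")
  if (length(parent_exon_lengths) < 2L)
    return("unknown")  # no junction to interrogate
  query <- if (!is.null(window))
    paste0(window$upstream, window$body, window$downstream) else body
  aln <- fit_align(pm, query, params)
  pa <- chars(aln$aligned_a); pq <- chars(aln$aligned_b)
  parent_pos <- cumsum(pa != "-")      # parent coordinate at each column
  junctions <- cumsum(parent_exon_lengths)
  junctions <- junctions[-length(junctions)]
  # length of the query insertion at each parent position (alignment may
  # place a junction gap a few bases off when insert edges happen to match)
  ins_at <- table(parent_pos[pa == "-"])
  verdicts <- character(length(junctions))
  for (j in seq_along(junctions)) {
    J <- junctions[j]
    near <- as.integer(names(ins_at)) >= J - 10L &
      as.integer(names(ins_at)) <= J + 10L
    ins_len <- if (any(near)) max(ins_at[near]) else 0L
    if (ins_len >= min_insert) { verdicts[j] <- "no"; next }
    span <- seq.int(max(1L, J - 9L), min(nchar(pm), J + 10L))
    span_cols <- which(pa != "-" & parent_pos %in% span)
    aligned <- sum(pq[span_cols] != "-")
    gaps <- sum(pq[span_cols] == "-") +
      sum(pa == "-" & parent_pos >= span[1] & parent_pos < span[length(span)])
    verdicts[j] <- if (aligned >= min_junction_cov && gaps <= max_junction_gaps)
      "yes" else "unknown"
  }
  if (any(verdicts == "no")) return("no")
  if (all(verdicts == "yes")) return("yes")
  "unknown"
}

# Parse a comma-separated exon-length field into an integer vector.
parse_exon_lengths <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  as.integer(strsplit(as.character(x), ",", fixed = TRUE)[[1]])
}

#' Read a parent-mRNA set (FASTA plus UTR/CDS span table)
#'
#' The companion TSV has columns `id`, `cds_start`, `cds_end` (1-based
#' inclusive within the mRNA) and `exon_lengths` (comma-separated).
#'
#' @param fasta_path Parent mRNA FASTA.
#' @param spans_path Companion span TSV.
#' @return A data.frame with columns `id`, `residues`, `cds_start`,
#'   `cds_end`, `exon_lengths`.
#' @export
read_parent_set <- function(fasta_path, spans_path) {
  recs <- read_fasta(fasta_path, alphabet = "dna")
  spans <- utils::read.delim(spans_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "cds_start", "cds_end", "exon_lengths")
  if (!all(need %in% names(spans)))
    stop("format error: span table must have columns ",
         paste(need, collapse = ", "))
  df <- merge(recs[, c("id", "residues")], spans[, need], by = "id")
  if (nrow(df) != nrow(recs))
    stop("annotation error: span table does not cover all mRNA records")
  df
}

# Per-region identity of a parent mRNA fitted into a query window.
region_identities <- function(aln, cds_start, cds_end, min_utr_cov = 30L) {
  pa <- chars(aln$aligned_a); pq <- chars(aln$aligned_b)
  parent_pos <- cumsum(pa != "-")
  plen <- max(parent_pos)
  ident <- function(lo, hi) {
    if (lo > hi) return(list(identity = NA_real_, coverage = 0L))
    cols <- which(pa != "-" & parent_pos >= lo & parent_pos <= hi)
    aligned <- cols[pq[cols] != "-"]
    list(identity = if (length(aligned) == 0L) NA_real_
         else mean(pa[aligned] == pq[aligned]),
         coverage = length(aligned))
  }
  cds <- ident(cds_start, cds_end)
  u5 <- ident(1L, cds_start - 1L)
  u3 <- ident(cds_end + 1L, plen)
  list(identity_cds = if (is.na(cds$identity)) 0 else cds$identity,
       identity_utr5 = if (u5$coverage >= min_utr_cov) u5$identity else NA_real_,
       identity_utr3 = if (u3$coverage >= min_utr_cov) u3$identity else NA_real_)
}

#' Assign the parental mRNA of a retro-copy
#'
#' The whole window (upstream + body + downstream) is fitted against each
#' candidate mRNA; the best parent maximizes identity over the CDS-aligned
#' region (ties broken by lexicographic candidate id).  UTR identities are
#' reported when at least `min_utr_cov` bases align; a recency flag is set
#' when both UTR identities reach 0.95.
#'
#' @param window A `retro_window`.
#' @param candidates Parent set data.frame (see [read_parent_set()]).
#' @param params Optional [align_params()].
#' @param min_utr_cov Minimum aligned bases for a UTR identity to be
#'   reported.
#' @return A list of class `parent_assignment`: `best_parent_id`,
#'   `identity_cds`, `identity_utr5`, `identity_utr3`, `margin`,
#'   `recency_flag`, and the per-candidate `table`.
#' @export
assign_parent <- function(window, candidates, params = NULL,
                          min_utr_cov = 30L) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0L)
    stop("argument error: empty candidate list")
  query <- paste0(window$upstream, window$body, window$downstream)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    aln <- fit_align(candidates$residues[i], query, params)
    ids <- region_identities(aln, candidates$cds_start[i],
                             candidates$cds_end[i], min_utr_cov)
    data.frame(parent_id = candidates$id[i],
               identity_cds = ids$identity_cds,
               identity_utr5 = ids$identity_utr5,
               identity_utr3 = ids$identity_utr3,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$identity_cds, tab$parent_id), , drop = FALSE]
  rownames(tab) <- NULL
  best <- tab[1L, ]
  margin <- if (nrow(tab) >= 2L) best$identity_cds - tab$identity_cds[2L]
            else NA_real_
  structure(list(best_parent_id = best$parent_id,
                 identity_cds = best$identity_cds,
                 identity_utr5 = best$identity_utr5,
                 identity_utr3 = best$identity_utr3,
                 margin = margin,
                 recency_flag = isTRUE(best$identity_utr5 >= 0.95) &&
                   isTRUE(best$identity_utr3 >= 0.95),
                 table = tab),
            class = "parent_assignment")
}

#' Scan one window for all retrogene hallmarks
#'
#' Composes the five detectors and derives the verdict: `retrogene` when the
#' CDS is complete and at least three of the four structural hallmarks
#' (intron loss, poly-A signal, poly-A tail, TSD) are present;
#' `retropseudogene` when the hallmarks are present but the CDS is broken
#' (premature stop or incomplete); `indeterminate` otherwise.
#'
#' @param window A `retro_window`.
#' @param parent Optional parent context: one row of a parent set
#'   data.frame (see [read_parent_set()]).  Enables the intron-loss call and
#'   the parent-length reference for premature stops.
#' @param tsd_opts,tail_opts Named lists overriding [find_tsd()] /
#'   [find_polya_tail()] defaults.
#' @param allow_attaaa Passed to [find_polya_signal()].
#' @return A list of class `retro_feature_report`.
#' @export
scan_retrogene <- function(window, parent = NULL, tsd_opts = list(),
                           tail_opts = list(), allow_attaaa = FALSE) {
  signal_pos <- find_polya_signal(window, allow_attaaa = allow_attaaa)
  tail_start <- do.call(find_polya_tail,
                        c(list(window = window, signal_pos = signal_pos),
                          tail_opts))
  tsd <- if (!is.na(tail_start))
    do.call(find_tsd, c(list(window = window, tail_start = tail_start),
                        tsd_opts)) else NULL
  expected_aa_len <- NULL
  exon_lengths <- NULL
  if (!is.null(parent)) {
    stopifnot(is.data.frame(parent), nrow(parent) == 1L)
    expected_aa_len <- as.integer((parent$cds_end - parent$cds_start + 1L) / 3L) - 1L
    exon_lengths <- parse_exon_lengths(parent$exon_lengths[[1]])
  }
  if (startsWith(window$body, "ATG") && nchar(window$body) >= 6L) {
    integ <- detect_cds_integrity(window$body, expected_aa_len)
  } else {
    integ <- list(premature_stop_codon_index = NA_integer_, full_cds = FALSE)
  }
  lacks_intron <- if (!is.null(parent))
    assess_intron_loss(window$body, parent$residues, exon_lengths,
                       window = window) else "unknown"
  hallmarks <- sum(lacks_intron == "yes", !is.na(signal_pos),
                   !is.na(tail_start), !is.null(tsd))
  verdict <- if (hallmarks >= 3L) {
    if (integ$full_cds && is.na(integ$premature_stop_codon_index))
      "retrogene" else "retropseudogene"
  } else "indeterminate"
  structure(list(locus_id = window$locus_id,
                 lacks_intron = lacks_intron,
                 polya_signal_pos = signal_pos,
                 polya_tail_start = tail_start,
                 tsd = tsd,
                 premature_stop_codon_index = integ$premature_stop_codon_index,
                 full_cds = integ$full_cds,
                 verdict = verdict),
            class = "retro_feature_report")
}

#' Scan many loci and build the hallmark report table
#'
#' Drives [extract_window()], [assign_parent()] (when a parent set is given;
#' the assigned parent supplies the intron and CDS-length context) and
#' [scan_retrogene()] over a loci table.
#'
#' @param genome Genome record or string.
#' @param loci Loci data.frame (0-based half-open).
#' @param parents Optional parent set data.frame.
#' @param up,down Window sizes.
#' @param ... Passed to [scan_retrogene()].
#' @return A list with `report` (one row per locus, Table-style Yes/No calls
#'   plus positions) and `assignments` (per-locus `parent_assignment`s, or
#'   `NULL`).
#' @export
scan_retrogenes <- function(genome, loci, parents = NULL, up = 200L,
                            down = 400L, ...) {
  rows <- vector("list", nrow(loci))
  assigns <- if (is.null(parents)) NULL else vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    w <- extract_window(genome, loci[i, , drop = FALSE], up, down)
    parent_row <- NULL
    if (!is.null(parents)) {
      pa <- assign_parent(w, parents)
      assigns[[i]] <- pa
      parent_row <- parents[parents$id == pa$best_parent_id, , drop = FALSE]
    }
    rep <- scan_retrogene(w, parent = parent_row, ...)
    rows[[i]] <- data.frame(
      locus_id = loci$locus_id[i],
      lack_of_intron = rep$lacks_intron,
      polya_signal = ifelse(is.na(rep$polya_signal_pos), "No", "Yes"),
      polya_signal_pos = rep$polya_signal_pos,
      polya_tail = ifelse(is.na(rep$polya_tail_start), "No", "Yes"),
      polya_tail_start = rep$polya_tail_start,
      tsd = ifelse(is.null(rep$tsd), "No", "Yes"),
      tsd_sequence = if (is.null(rep$tsd)) NA_character_ else rep$tsd$sequence,
      tsd_length = if (is.null(rep$tsd)) NA_integer_ else rep$tsd$length,
      premature_stop = ifelse(is.na(rep$premature_stop_codon_index),
                              "No", "Yes"),
      premature_stop_codon = rep$premature_stop_codon_index,
      full_cds = rep$full_cds,
      parent_id = if (is.null(parent_row)) NA_character_ else parent_row$id,
      verdict = rep$verdict,
      stringsAsFactors = FALSE)
  }
  if (!is.null(assigns)) names(assigns) <- loci$locus_id
  list(report = do.call(rbind, rows), assignments = assigns)
}
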