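# Two-parent chimeric gene detection.
#
# A query is modeled as parent A up to a breakpoint and parent B after it.
# Per-position match profiles of the query against each parent (projected
# onto ungapped query coordinates) are combined; the breakpoint maximizing
# the two-parent match total is compared with the best single-parent fit.
# The character 'X' (used to mark frameshifted segments in translated
# queries) never counts as a match.

# Per-position match vector of query vs one parent, in ungapped query
# coordinates.
match_profile <- function(query, parent, params = NULL) {
  aln <- global_align(query, parent, params)
  cq <- chars(aln$aligned_a); cp <- chars(aln$aligned_b)
  qpos <- cumsum(cq != "-")
  keep <- cq != "-"
  out <- logical(max(qpos))
  hit <- keep & cp != "-" & cq == cp & cq != "X" & cp != "X"
  out[qpos[hit]] <- TRUE
  out
}

#' Locate the breakpoint of a two-parent chimeric sequence
#'
#' For every breakpoint `b` (0-based, in ungapped query coordinates) the
#' two-parent match total `M(b) = matches(query, left parent on [0, b)) +
#' matches(query, right parent on [b, L))` is computed for both parent
#' orders; the score gain is the best two-parent total minus the best
#' single-parent total.  Within the run of columns where the parents agree
#' the breakpoint is unidentifiable, so the reported breakpoint is the
#' midpoint of the maximizing plateau (the unbiased choice).
#'
#' @param query,parent_a,parent_b Sequences (records or strings), same
#'   alphabet; parents must differ.
#' @param params Optional [align_params()].
#' @param min_gain Minimum score gain (matched positions) to call a chimera.
#' @return A list of class `chimera_result`: `is_chimeric`,
#'   `breakpoint_col` (0-based; position where the right parent takes over),
#'   `left_parent_id`, `right_parent_id`, `score_gain`, `left_identity`,
#'   `right_identity`.
#' @export
breakpoint_scan <- function(query, parent_a, parent_b, params = NULL,
                            min_gain = 5L) {
  sa <- as_residues(parent_a); sb <- as_residues(parent_b)
  if (identical(sa, sb))
    stop("degenerate-parents error: parents are identical")
  ida <- record_id(parent_a, "parent_a"); idb <- record_id(parent_b, "parent_b")
  ma <- match_profile(query, sa, params)
  mb <- match_profile(query, sb, params)
  L <- length(ma)
  stopifnot(length(mb) == L)
  ca <- c(0L, cumsum(ma)); cb <- c(0L, cumsum(mb))
  tot_a <- ca[L + 1L]; tot_b <- cb[L + 1L]
  m_ab <- ca + (tot_b - cb)          # A left of b, B right; index i = b + 1
  m_ba <- cb + (tot_a - ca)
  best_ab <- max(m_ab); best_ba <- max(m_ba)
  plateau_mid <- function(v) {
    idx <- which(v == max(v))
    idx[ceiling(length(idx) / 2)] - 1L
  }
  if (best_ab >= best_ba) {
    b <- plateau_mid(m_ab)
    left_id <- ida; right_id <- idb
    cl <- ca; cr <- cb; tot_r <- tot_b; best <- best_ab
  } else {
    b <- plateau_mid(m_ba)
    left_id <- idb; right_id <- ida
    cl <- cb; cr <- ca; tot_r <- tot_a; best <- best_ba
  }
  gain <- best - max(tot_a, tot_b)
  structure(list(
    query_id = record_id(query, "query"),
    is_chimeric = gain >= min_gain,
    breakpoint_col = if (gain >= min_gain) b else NA_integer_,
    left_parent_id = left_id, right_parent_id = right_id,
    score_gain = gain,
    left_identity = if (b > 0L) cl[b + 1L] / b else NA_real_,
    right_identity = if (b < L) (tot_r - cr[b + 1L]) / (L - b) else NA_real_,
    breakpoint_raw = b),
    class = "chimera_result")
}

#' Screen queries against all parent-group pairs
#'
#' Each query is tested against every unordered pair of group
#' representatives; the best result (largest score gain, ties broken by the
#' lexicographically smallest parent pair) is returned per query.
#'
#' @param queries Data.frame of query records.
#' @param parent_groups Data.frame of group representative records (column
#'   `id` names the group).
#' @param params Optional [align_params()].
#' @param min_gain Passed to [breakpoint_scan()].
#' @return A list of `chimera_result`, one per query (empty for no queries).
#' @export
chimera_screen <- function(queries, parent_groups, params = NULL,
                           min_gain = 5L) {
  stopifnot(is.data.frame(parent_groups), nrow(parent_groups) >= 2L)
  if (is.null(queries) || nrow(queries) == 0L) return(list())
  pg <- parent_groups[order(parent_groups$id), , drop = FALSE]
  out <- vector("list", nrow(queries))
  for (q in seq_len(nrow(queries))) {
    best <- NULL
    for (i in seq_len(nrow(pg) - 1L)) {
      for (j in seq.int(i + 1L, nrow(pg))) {
        res <- breakpoint_scan(queries[q, , drop = FALSE],
                               pg[i, , drop = FALSE], pg[j, , drop = FALSE],
                               params, min_gain)
        if (is.null(best) || res$score_gain > best$score_gain) best <- res
      }
    }
    out[[q]] <- best
  }
  names(out) <- queries$id
  out
}

#' Tabulate chimera screen results
#'
#' @param results List of `chimera_result` from [chimera_screen()].
#' @return A data.frame, one row per query.
#' @export
chimera_report <- function(results) {
  if (length(results) == 0L)
    return(data.frame(query_id = character(0), is_chimeric = logical(0),
                      breakpoint_col = integer(0),
                      left_parent_id = character(0),
                      right_parent_id = character(0),
                      score_gain = numeric(0), left_identity = numeric(0),
                      right_identity = numeric(0)))
  do.call(rbind, lapply(results, function(r)
    data.frame(query_id = r$query_id, is_chimeric = r$is_chimeric,
               breakpoint_col = r$breakpoint_col,
               left_parent_id = r$left_parent_id,
               right_parent_id = r$right_parent_id,
               score_gain = r$score_gain,
               left_identity = r$left_identity,
               right_identity = r$right_identity,
               stringsAsFactors = FALSE)))
}
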