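# Distance-based phylogeny: site-coverage (partial-deletion) column filter,
# pairwise distances (p, Poisson-corrected, JC69), neighbor-joining via
# ape::nj, and nonparametric bootstrap supports.
#
# Ambiguity characters (N for DNA, X for protein, and '?') count as gaps
# both for column coverage and for pairwise distance computation.

ambiguous_chars <- function(alphabet) {
  c("-", "?", if (alphabet == "dna") "N" else "X")
}

#' Partial-deletion column filter
#'
#' Retains exactly the columns where the fraction of rows with an
#' unambiguous residue is at least `min_coverage` (the comparison uses
#' `>=`).  Row order is preserved; the filter is idempotent.
#'
#' @param msa An `msa`.
#' @param min_coverage Minimum site coverage (default 0.95).
#' @return The filtered `msa`.
#' @export
partial_deletion_filter <- function(msa, min_coverage = 0.95) {
  m <- msa_matrix(msa)
  bad <- ambiguous_chars(msa$alphabet)
  cov <- colMeans(!matrix(m %in% bad, nrow(m), ncol(m)))
  keep <- cov >= min_coverage
  if (!any(keep))
    stop("empty-alignment error: all columns removed by the coverage filter")
  out <- msa
  out$seqs <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  out
}

#' Pairwise distance matrix from an alignment
#'
#' Gap and ambiguity positions are excluded pairwise (complete deletion per
#' pair).  Models: `p` = mismatches / compared sites; `poisson` =
#' `-ln(1 - p)` (protein); `jc69` = `-(3/4) ln(1 - 4p/3)` (DNA).  Saturated
#' pairs (logarithm argument <= 0) are capped at `max_dist` and flagged in
#' the `"saturated"` attribute.
#'
#' @param msa An `msa` with at least 3 sequences.
#' @param model `"p"`, `"poisson"` or `"jc69"`.
#' @param max_dist Cap for saturated distances.
#' @return A symmetric numeric matrix with taxa dimnames.
#' @export
distance_matrix <- function(msa, model = c("p", "poisson", "jc69"),
                            max_dist = 5) {
  model <- match.arg(model)
  m <- msa_matrix(msa)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 sequences")
  bad <- ambiguous_chars(msa$alphabet)
  valid <- !matrix(m %in% bad, n, ncol(m))
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  saturated <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      sites <- valid[i, ] & valid[j, ]
      ns <- sum(sites)
      if (ns == 0L)
        stop("zero comparable sites for pair ", msa$ids[i], " / ", msa$ids[j])
      p <- sum(m[i, sites] != m[j, sites]) / ns
      val <- switch(model,
                    p = p,
                    poisson = if (p >= 1) NA_real_ else -log(1 - p),
                    jc69 = if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3))
      if (is.na(val) || val > max_dist) {
        val <- max_dist
        saturated <- c(saturated, paste(msa$ids[i], msa$ids[j], sep = "|"))
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  attr(d, "saturated") <- saturated
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining on a symmetric distance matrix.
#' Negative branch-length estimates are clamped to zero and flagged in the
#' `"clamped_branches"` attribute.
#'
#' @param D Symmetric distance matrix with taxa dimnames.
#' @return An unrooted ape `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || !isSymmetric(unname(D)))
    stop("input error: distance matrix must be symmetric")
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(D))
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_branches") <- clamped
  tr
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Applies the coverage filter once, builds the reference NJ tree, then
#' resamples alignment columns with replacement `replicates` times,
#' rebuilding the tree each time.  Support of an internal edge is the
#' percentage of replicates containing the same bipartition, rounded to an
#' integer and stored as the node label.  Fully reproducible for a given
#' seed.
#'
#' @param msa An `msa` with at least 4 sequences.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param model Distance model (see [distance_matrix()]).
#' @param min_coverage Passed to [partial_deletion_filter()].
#' @return The reference `phylo` tree with integer supports in
#'   `node.label`.
#' @export
bootstrap_support <- function(msa, replicates = 1000L, seed = 1L,
                              model = c("p", "poisson", "jc69"),
                              min_coverage = 0.95) {
  model <- match.arg(model)
  if (replicates < 1L) stop("argument error: replicates must be >= 1")
  if (length(msa$ids) < 4L) stop("need at least 4 sequences")
  filt <- partial_deletion_filter(msa, min_coverage)
  ref <- nj_tree(distance_matrix(filt, model))
  m <- msa_matrix(filt)
  L <- ncol(m)
  boot_trees <- with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      idx <- sample.int(L, L, replace = TRUE)
      bm <- m[, idx, drop = FALSE]
      bmsa <- filt
      bmsa$seqs <- apply(bm, 1L, paste, collapse = "")
      nj_tree(distance_matrix(bmsa, model))
    })
  })
  counts <- ape::prop.clades(ref, boot_trees, rooted = FALSE)
  support <- round(100 * counts / replicates)
  lab <- as.character(support)
  lab[is.na(lab)] <- ""
  ref$node.label <- lab
  attr(ref, "replicates") <- replicates
  ref
}

#' Write a distance matrix to TSV
#'
#' @param D Distance matrix from [distance_matrix()].
#' @param path Output path.
#' @export
write_distances <- function(D, path) {
  df <- data.frame(taxon = rownames(D), as.data.frame(D, check.names = FALSE),
                   check.names = FALSE)
  write_report(df, path)
}
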