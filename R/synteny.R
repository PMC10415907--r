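# Synteny classification: canonical IFITM cluster versus scattered
# retrogene candidates, per-species cluster order, and cross-species
# shared-flank groups.

# "BAGALNT4", a spelling seen in the literature, is an alias of B4GALNT4.
ANCHOR_ALIASES <- c(BAGALNT4 = "B4GALNT4")

canon_gene_name <- function(x) {
  x <- toupper(x)
  hit <- match(x, names(ANCHOR_ALIASES))
  x[!is.na(hit)] <- ANCHOR_ALIASES[hit[!is.na(hit)]]
  x
}

#' Cluster specification for synteny classification
#'
#' @param anchor_genes Ordered character vector of flanking anchor genes
#'   delimiting the canonical cluster (default PGGHG, B4GALNT4, CTSD).
#' @param family_pattern Regular expression identifying family members by
#'   `gene_name` (case-insensitive).
#' @param max_dist Maximum distance (bp) from the anchor span within which a
#'   family locus still counts as canonical.  Default 500 kb.
#' @return A list of class `cluster_spec`.
#' @export
cluster_spec <- function(anchor_genes = c("PGGHG", "B4GALNT4", "CTSD"),
                         family_pattern = "IFITM", max_dist = 5e5) {
  if (length(anchor_genes) < 1L) stop("need at least one anchor gene")
  structure(list(anchor_genes = canon_gene_name(anchor_genes),
                 family_pattern = family_pattern,
                 max_dist = max_dist),
            class = "cluster_spec")
}

#' Classify family loci as canonical-cluster members or scattered
#'
#' A family locus is canonical iff it lies on the same contig as at least
#' one anchor gene of its species and within
#' `[min(anchor starts) - max_dist, max(anchor ends) + max_dist]` of the
#' anchors on that contig.  All other family loci are scattered.  Species
#' with no anchor locus at all have every member classified scattered and
#' carry a warning flag (mirroring chromosomal-rearrangement or assembly
#' cases rather than raising an error).
#'
#' @param loci Internal loci data.frame (see [read_loci_table()]).
#' @param spec A [cluster_spec()].
#' @return A list of class `synteny_report` with elements `loci` (the input
#'   family loci plus columns `class`, `intron_resident`, `no_anchor_warning`),
#'   `anchors` (anchor loci found) and `single_member_species` (species with
#'   exactly one canonical IR member, flagged for possible assembly gaps).
#' @export
classify_loci <- function(loci, spec = cluster_spec()) {
  stopifnot(is.data.frame(loci))
  gn <- canon_gene_name(loci$gene_name)
  is_anchor <- gn %in% spec$anchor_genes
  is_family <- grepl(spec$family_pattern, gn, ignore.case = TRUE)
  fam <- loci[is_family & !is_anchor, , drop = FALSE]
  anchors <- loci[is_anchor, , drop = FALSE]
  cls <- character(nrow(fam))
  warn <- logical(nrow(fam))
  for (i in seq_len(nrow(fam))) {
    sp <- fam$species[i]
    a <- anchors[anchors$species == sp, , drop = FALSE]
    if (nrow(a) == 0L) {
      cls[i] <- "scattered"; warn[i] <- TRUE
      next
    }
    a <- a[a$contig == fam$contig[i], , drop = FALSE]
    if (nrow(a) == 0L) {
      cls[i] <- "scattered"
      next
    }
    lo <- min(a$start) - spec$max_dist
    hi <- max(a$end) + spec$max_dist
    cls[i] <- if (fam$start[i] >= lo && fam$end[i] <= hi)
      "canonical" else "scattered"
  }
  fam$class <- cls
  fam$intron_resident <- !is.na(fam$host_gene) & nzchar(fam$host_gene)
  fam$no_anchor_warning <- warn
  ord <- order(fam$species, fam$contig, fam$start)
  fam <- fam[ord, , drop = FALSE]
  rownames(fam) <- NULL
  canon_per_sp <- table(fam$species[fam$class == "canonical"])
  structure(list(loci = fam, anchors = anchors,
                 single_member_species =
                   names(canon_per_sp)[canon_per_sp == 1L],
                 spec = spec),
            class = "synteny_report")
}

#' Group scattered loci sharing both flanking genes across species
#'
#' Loci whose unordered `(upstream_gene, downstream_gene)` pair is shared by
#' loci from at least one other species are grouped; singleton flank pairs
#' are omitted.
#'
#' @param loci Loci data.frame (typically the scattered subset).
#' @return A list of character vectors of `locus_id`s, one per shared-flank
#'   group.
#' @export
shared_flank_groups <- function(loci) {
  stopifnot(is.data.frame(loci))
  has_flanks <- !is.na(loci$upstream_gene) & !is.na(loci$downstream_gene) &
    nzchar(loci$upstream_gene) & nzchar(loci$downstream_gene)
  x <- loci[has_flanks, , drop = FALSE]
  if (nrow(x) == 0L) return(list())
  key <- vapply(seq_len(nrow(x)), function(i) {
    paste(sort(canon_gene_name(c(x$upstream_gene[i], x$downstream_gene[i]))),
          collapse = "|")
  }, "")
  groups <- split(seq_len(nrow(x)), key)
  out <- list()
  for (g in groups) {
    if (length(g) < 2L) next
    if (length(unique(x$species[g])) < 2L) next
    out[[length(out) + 1L]] <- x$locus_id[g][order(x$species[g], x$locus_id[g])]
  }
  out[order(vapply(out, function(v) v[1], ""))]
}

#' Per-species order and orientation of the canonical cluster
#'
#' @param report A `synteny_report` from [classify_loci()].
#' @return A named list (one element per species) of data.frames with
#'   columns `gene_name`, `strand`, `start`, ordered by start coordinate.
#' @export
cluster_order <- function(report) {
  stopifnot(inherits(report, "synteny_report"))
  canon <- report$loci[report$loci$class == "canonical", , drop = FALSE]
  lapply(split(canon, canon$species), function(d) {
    d <- d[order(d$start), c("gene_name", "strand", "start")]
    rownames(d) <- NULL
    d
  })
}

#' Write the synteny reports to TSV
#'
#' @param report A `synteny_report`.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_synteny_report <- function(report, dir = ".") {
  p1 <- file.path(dir, "synteny_report.tsv")
  out <- report$loci
  out$start <- out$start + 1L  # user-facing tables are 1-based inclusive
  write_report(out, p1)
  groups <- shared_flank_groups(report$loci[report$loci$class == "scattered", ,
                                            drop = FALSE])
  gdf <- if (length(groups) == 0L)
    data.frame(group = integer(0), locus_id = character(0))
  else
    data.frame(group = rep(seq_along(groups), lengths(groups)),
               locus_id = unlist(groups))
  p2 <- file.path(dir, "shared_flanks.tsv")
  write_report(gdf, p2)
  invisible(c(p1, p2))
}
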