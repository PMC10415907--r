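# Sequence, loci-table and tree I/O.
#
# Conventions owned by this file:
#   * FASTA records come back as a data.frame with columns id, description,
#     residues (uppercased).  Order is preserved.
#   * The loci table on disk is TSV with 1-based inclusive coordinates (the
#     convention of genome browsers); internally every locus is 0-based
#     half-open.  read/write are exact inverses.
#   * Trees are ape "phylo" objects; bootstrap supports travel as internal
#     node labels in Newick.

LOCI_COLUMNS <- c("locus_id", "species", "contig", "start", "end", "strand",
                  "gene_name", "exon_count", "upstream_gene",
                  "downstream_gene", "host_gene")

#' Read a FASTA file
#'
#' Reads plain (optionally multi-line, CRLF-tolerant) FASTA.  Residues are
#' uppercased and validated against the declared alphabet; `"auto"` infers
#' DNA when every residue is one of `ACGTN-` and protein otherwise.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of `"auto"`, `"dna"`, `"protein"`.
#' @param aligned Logical; allow the gap character `-` in residues.
#' @return A data.frame with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein"),
                       aligned = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L)
    stop("format error: not a FASTA file (no records): ", path)
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  res_full <- toupper(as.character(x))
  if (any(!nzchar(res_full)))
    stop("format error: record '", id[!nzchar(res_full)][1],
         "' has no residues")
  if (any(duplicated(id)))
    warning("duplicated FASTA ids: ",
            paste(unique(id[duplicated(id)]), collapse = ", "))
  for (i in seq_along(id)) {
    ab <- if (alphabet == "auto") infer_alphabet(res_full[i]) else alphabet
    check_alphabet(res_full[i], ab, id = id[i], allow_gap = aligned)
  }
  data.frame(id = id, description = description, residues = res_full,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write records to FASTA
#'
#' @param records Data.frame with columns `id`, `residues` (optionally
#'   `description`).
#' @param path Output path.
#' @param width Line width for the sequence body.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records) &&
                nzchar(records$description[i]))
      paste0(" ", records$description[i]) else ""
    writeLines(paste0(">", records$id[i], desc), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a gene-loci annotation table
#'
#' The file is TSV with header columns `locus_id species contig start end
#' strand gene_name exon_count upstream_gene downstream_gene host_gene`,
#' coordinates 1-based inclusive.  Internally coordinates are converted to
#' 0-based half-open; blank optional fields become `NA`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of loci with 0-based half-open `start`/`end`.
#' @export
read_loci_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "."))
  missing_cols <- setdiff(LOCI_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop("format error: loci table missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[, LOCI_COLUMNS]
  if (!all(df$strand %in% c("+", "-")))
    stop("format error: unknown strand symbol '",
         df$strand[!(df$strand %in% c("+", "-"))][1], "'")
  df$start <- as.integer(df$start) - 1L   # 1-based inclusive -> 0-based half-open
  df$end <- as.integer(df$end)
  bad <- df$start < 0L | df$start >= df$end
  if (any(bad))
    stop("coordinate error: start >= end (after conversion) for locus ",
         df$locus_id[bad][1])
  df$exon_count <- suppressWarnings(as.integer(df$exon_count))
  df
}

#' Write a gene-loci table (1-based inclusive on disk)
#'
#' @param loci Internal loci data.frame (0-based half-open).
#' @param path Output path.
#' @export
write_loci_table <- function(loci, path) {
  out <- loci[, LOCI_COLUMNS]
  out$start <- out$start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a tree to Newick text
#'
#' Branch lengths are emitted; internal-node labels (e.g. bootstrap supports)
#' are kept.  Round-trips through [read_newick()] to an identical topology
#' and branch lengths.
#'
#' @param tree An ape `phylo` object.
#' @param path Optional path; when `NULL` the Newick string is returned.
#' @return The Newick text (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("structure error: tree has no branch lengths")
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#'
#' @param x Path to a Newick file, or a Newick string.
#' @return An ape `phylo` object.
#' @export
read_newick <- function(x) {
  tr <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tr)) stop("format error: cannot parse Newick input")
  tr
}

#' Write a TSV report with a fixed column order
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @export
write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the function, parameters and package version of a run so that
#' every reported call is auditable.
#'
#' @param path Output path.
#' @param step Name of the pipeline step.
#' @param params Named list of parameters.
#' @export
write_manifest <- function(path, step, params = list()) {
  manifest <- list(
    step = step,
    package = "retroIFITM",
    version = as.character(utils::packageVersion("retroIFITM")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
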