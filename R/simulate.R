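# Synthetic-data generators with machine-readable ground truth.
#
# The generators emulate the processes the analysis modules are built to
# detect: a host contig carrying a canonical gene cluster (anchor genes
# PGGHG / B4GALNT4 / CTSD plus intron-bearing IFITM family genes),
# TPRT-style retrotransposition of spliced parent mRNAs (target-site
# duplication, poly-A signal and tail, optional 5' truncation and
# pseudogenizing mutations), two-parent chimeras with known breakpoints,
# and sequence evolution along a known tree.  Every emitted feature is
# recorded in a truth object that tests verify by direct string inspection.

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

#' Simulation configuration
#'
#' @param seed Integer RNG seed (required; the generators have no implicit
#'   randomness).
#' @param genome_len Host contig length target (bp).
#' @param gc Background GC content.
#' @param n_insertions Number of retro-insertions for
#'   [simulate_retrogenome()].
#' @param tsd_len_range Target-site duplication length range (bp).
#' @param tail_len_range Poly-A tail length range (bp).
#' @param copy_mutation_rate Per-site substitution rate applied to the
#'   inserted copy (mRNA + tail).
#' @param nonsense_probability Probability that a retro-copy receives a
#'   planted premature stop codon.
#' @param truncation_probability Probability of 5' truncation of the copy.
#' @param signal_tail_gap_range Distance range between the poly-A signal
#'   end and the 3' UTR end (bp).
#' @param n_family_genes Number of intron-bearing IR-family parent genes in
#'   the cluster.
#' @param paralog_divergence Per-site divergence between the IR-family
#'   paralogs (the second and later family genes are derived from the
#'   first).
#' @param aa_len Parent protein length (amino acids, excluding the stop).
#' @param utr5_len,utr3_len Parent UTR lengths (bp).
#' @param n_exons Exons per parent gene (>= 2 so intron loss is observable).
#' @param intron_len_range Intron length range (bp).
#' @param insertion_buffer Minimum distance between an insertion site and
#'   any existing locus or previous insertion (bp).
#' @param minus_strand_prob Probability that a retro-copy integrates on the
#'   minus strand.
#' @param species,contig Labels used in the emitted loci table.
#' @param retro_contig Name of the background contig that receives the
#'   retro-insertions in [simulate_retrogenome()] (retrogenes land away
#'   from the cluster chromosome).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, genome_len = 100000L, gc = 0.5,
                       n_insertions = 10L, tsd_len_range = c(6L, 20L),
                       tail_len_range = c(10L, 50L),
                       copy_mutation_rate = 0, nonsense_probability = 0,
                       truncation_probability = 0,
                       signal_tail_gap_range = c(0L, 30L),
                       n_family_genes = 3L, paralog_divergence = 0.05,
                       aa_len = 120L,
                       utr5_len = 60L, utr3_len = 90L, n_exons = 3L,
                       intron_len_range = c(80L, 300L),
                       insertion_buffer = 700L, minus_strand_prob = 0.5,
                       species = "SimSpecies", contig = "chr1",
                       retro_contig = "chr2") {
  if (missing(seed)) stop("config error: seed is required")
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2]
  stopifnot(rng_ok(tsd_len_range), rng_ok(tail_len_range),
            rng_ok(signal_tail_gap_range), rng_ok(intron_len_range),
            gc >= 0, gc <= 1, copy_mutation_rate >= 0,
            copy_mutation_rate <= 1, nonsense_probability >= 0,
            nonsense_probability <= 1, truncation_probability >= 0,
            truncation_probability <= 1, n_exons >= 2L, aa_len >= 20L)
  if (utr3_len < 6L + signal_tail_gap_range[2])
    stop("config error: utr3_len too short for the poly-A signal placement")
  structure(mget(names(formals(sim_config))), class = "sim_config")
}

# Random DNA with the requested GC content.
random_dna <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Substitute each site independently with probability `rate` (to a
# different residue).
mutate_seq <- function(s, rate, letters = DNA_LETTERS) {
  if (rate <= 0 || nchar(s) == 0L) return(list(seq = s, positions = integer(0)))
  cs <- chars(s)
  hit <- which(stats::runif(length(cs)) < rate)
  for (i in hit) {
    cs[i] <- sample(setdiff(letters, cs[i]), 1L)
  }
  list(seq = paste(cs, collapse = ""), positions = hit)
}

# An intron-bearing parent gene with a planted poly-A signal in the 3' UTR.
make_parent_gene <- function(name, config) {
  cds <- paste0("ATG",
                paste(sample(SENSE_CODONS, config$aa_len - 1L, replace = TRUE),
                      collapse = ""),
                sample(STOP_CODONS, 1L))
  utr5 <- random_dna(config$utr5_len, config$gc)
  gap <- sample(seq.int(config$signal_tail_gap_range[1],
                        config$signal_tail_gap_range[2]), 1L)
  pre_len <- config$utr3_len - 6L - gap
  # The stretch between the signal and the tail carries no A, so the tail
  # start is a well-defined ground truth (the first A after the signal).
  repeat {
    utr3 <- paste0(random_dna(pre_len, config$gc), "AATAAA",
                   if (gap > 0L)
                     paste(sample(c("C", "G", "T"), gap, replace = TRUE),
                           collapse = "") else "")
    first <- as.integer(regexpr("AATAAA", utr3, fixed = TRUE))
    if (first == pre_len + 1L) break
  }
  mrna <- paste0(utr5, cds, utr3)
  L <- nchar(mrna)
  # exon cut points at least 30 bp from the ends and from each other, so
  # every junction can be interrogated by the intron-loss rule
  repeat {
    cuts <- sort(sample(seq.int(30L, L - 30L), config$n_exons - 1L))
    if (config$n_exons == 2L || min(diff(cuts)) >= 30L) break
  }
  exon_lengths <- diff(c(0L, cuts, L))
  introns <- vapply(seq_len(config$n_exons - 1L), function(i)
    random_dna(sample(seq.int(config$intron_len_range[1],
                              config$intron_len_range[2]), 1L), config$gc), "")
  exons <- substring(mrna, c(0L, cuts) + 1L, c(cuts, L))
  gene_seq <- paste0(paste0(exons[-config$n_exons], introns, collapse = ""),
                     exons[config$n_exons])
  list(name = name, mrna = mrna, gene_seq = gene_seq,
       cds_start = config$utr5_len + 1L,
       cds_end = config$utr5_len + nchar(cds),
       exon_lengths = exon_lengths,
       aa_len = config$aa_len,
       utr5_len = config$utr5_len, utr3_len = config$utr3_len,
       signal_pos = pre_len,        # 0-based within the downstream window
       signal_gap = gap)
}

# Derive a paralog of an existing parent gene: the mRNA diverges at
# `divergence` per site, but the canonical start, the final stop codon, the
# poly-A signal and the signal-to-tail spacer are preserved, and mutations
# never create an in-frame stop (paralogs keep an intact CDS) or a
# spurious upstream poly-A signal.  Introns are drawn fresh.
derive_paralog <- function(parent, name, divergence, config) {
  cds_len <- parent$cds_end - parent$cds_start + 1L
  cds <- substr(parent$mrna, parent$cds_start, parent$cds_end)
  repeat {
    mid <- mutate_seq(substr(cds, 4L, cds_len - 3L), divergence)$seq
    new_cds <- paste0("ATG", mid, substr(cds, cds_len - 2L, cds_len))
    if (is.na(first_stop_index(substr(new_cds, 1L, cds_len - 3L)))) break
  }
  utr5 <- mutate_seq(substr(parent$mrna, 1L, parent$utr5_len), divergence)$seq
  utr3 <- substr(parent$mrna, parent$cds_end + 1L, nchar(parent$mrna))
  pre_len <- parent$signal_pos
  repeat {
    pre <- mutate_seq(substr(utr3, 1L, pre_len), divergence)$seq
    new_utr3 <- paste0(pre, substr(utr3, pre_len + 1L, nchar(utr3)))
    if (as.integer(regexpr("AATAAA", new_utr3, fixed = TRUE)) == pre_len + 1L)
      break
  }
  mrna <- paste0(utr5, new_cds, new_utr3)
  introns <- vapply(seq_along(parent$exon_lengths)[-1L], function(i)
    random_dna(sample(seq.int(config$intron_len_range[1],
                              config$intron_len_range[2]), 1L), config$gc), "")
  cuts <- cumsum(parent$exon_lengths)
  exons <- substring(mrna, c(0L, cuts[-length(cuts)]) + 1L, cuts)
  gene_seq <- paste0(paste0(exons[-length(exons)], introns, collapse = ""),
                     exons[length(exons)])
  out <- parent
  out$name <- name
  out$mrna <- mrna
  out$gene_seq <- gene_seq
  out
}

# First stop codon of an in-frame CDS, by direct string inspection.
first_stop_index <- function(cds) {
  n <- nchar(cds) %/% 3L
  for (i in seq_len(n)) {
    if (substr(cds, 3L * i - 2L, 3L * i) %in% STOP_CODONS) return(i)
  }
  NA_integer_
}

#' Simulate a host contig with a canonical gene cluster
#'
#' Emits one contig carrying, in order, the anchor gene PGGHG, IFITM5, the
#' anchor B4GALNT4, `n_family_genes` intron-bearing IR-family genes,
#' IFITM10 and the anchor CTSD, separated by background spacers, followed
#' by background sequence up to `genome_len`.  Deterministic for a given
#' seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `genome_sim`: `genome` (record data.frame),
#'   `loci` (internal 0-based coordinates), `parents` (parent-set
#'   data.frame, see [read_parent_set()]), `parent_genes` (full gene
#'   objects) and `truth`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_genome_core(config))
}

simulate_genome_core <- function(config) {
  ir_names <- paste0("IFITM", c(3L, 1L, 2L, 11L:20L))[seq_len(config$n_family_genes)]
  gene_plan <- c("PGGHG", "IFITM5", "B4GALNT4", ir_names, "IFITM10", "CTSD")
  anchor <- gene_plan %in% c("PGGHG", "B4GALNT4", "CTSD")
  single_exon <- gene_plan %in% c("PGGHG", "B4GALNT4", "CTSD")
  first_ir <- NULL
  genes <- lapply(seq_along(gene_plan), function(i) {
    nm <- gene_plan[i]
    if (single_exon[i])
      return(list(name = nm, gene_seq = random_dna(500L, config$gc),
                  exon_count = 1L))
    g <- if (nm %in% ir_names && !is.null(first_ir))
      derive_paralog(first_ir, nm, config$paralog_divergence, config)
    else make_parent_gene(nm, config)
    if (nm == ir_names[1]) first_ir <<- g
    c(g, list(exon_count = config$n_exons))
  })
  pieces <- character(0)
  cursor <- 0L
  lead <- random_dna(2000L, config$gc)
  pieces <- c(pieces, lead); cursor <- cursor + nchar(lead)
  loci <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    strand <- if (anchor[i] || g$name %in% c("IFITM5", "IFITM10")) "+"
              else sample(c("+", "-"), 1L)
    seq_i <- if (strand == "+") g$gene_seq else revcomp(g$gene_seq)
    loci[[i]] <- data.frame(
      locus_id = paste0("cluster_", g$name), species = config$species,
      contig = config$contig, start = cursor,
      end = cursor + nchar(seq_i), strand = strand, gene_name = g$name,
      exon_count = g$exon_count,
      upstream_gene = if (i > 1L) gene_plan[i - 1L] else NA_character_,
      downstream_gene = if (i < length(gene_plan)) gene_plan[i + 1L]
                        else NA_character_,
      host_gene = NA_character_, stringsAsFactors = FALSE)
    pieces <- c(pieces, seq_i); cursor <- cursor + nchar(seq_i)
    spacer <- random_dna(sample(200:800, 1L), config$gc)
    pieces <- c(pieces, spacer); cursor <- cursor + nchar(spacer)
  }
  cluster_end <- cursor
  if (config$genome_len < cluster_end + 4000L)
    stop("config error: genome too short to host the cluster")
  pieces <- c(pieces, random_dna(config$genome_len - cursor, config$gc))
  genome <- paste(pieces, collapse = "")
  loci <- do.call(rbind, loci)
  pg <- genes[!single_exon]
  parents <- do.call(rbind, lapply(pg, function(g)
    data.frame(id = g$name, residues = g$mrna, cds_start = g$cds_start,
               cds_end = g$cds_end,
               exon_lengths = paste(g$exon_lengths, collapse = ","),
               stringsAsFactors = FALSE)))
  names(pg) <- vapply(pg, function(g) g$name, "")
  structure(list(
    genome = data.frame(id = config$contig, description = "",
                        residues = genome, stringsAsFactors = FALSE),
    loci = loci, parents = parents, parent_genes = pg,
    truth = list(cluster_span = c(0L, cluster_end),
                 background_start = cluster_end,
                 gc = config$gc, seed = config$seed)),
    class = "genome_sim")
}

# Truth well-definedness guards for a candidate insertion site, evaluated
# in window (coding-orientation) space by direct string inspection:
#   g1  the TSD must not begin with A (it would be absorbed into the tail);
#   g2  fewer than 6 of the 8 bases following the TSD start are A (so the
#       tail-run scan stops exactly at the TSD);
#   g3  the TSD k-mer occurs exactly once in the 200 bp upstream window
#       (otherwise "the" upstream copy is ambiguous);
#   g4  the three base pairs immediately after the two copies differ, so
#       the planted repeat cannot be extended by chance.
# Sites violating a guard are resampled; the guards define when the planted
# TSD is a recoverable, unambiguous ground truth.
site_guards_ok <- function(g, pos, k, strand, utr5_rem_seq, up_win = 200L) {
  site <- substr(g, pos + 1L, pos + k)
  if (strand == "+") {
    tsd_w <- site
    ext <- substr(g, pos + k + 1L, pos + k + 8L)
  } else {
    tsd_w <- revcomp(site)
    ext <- revcomp(substr(g, pos - 7L, pos))
  }
  if (substr(tsd_w, 1L, 1L) == "A") return(FALSE)
  t8 <- chars(substr(paste0(tsd_w, ext), 2L, 9L))
  if (sum(t8 == "A") >= 6L) return(FALSE)
  up_keep <- up_win - nchar(utr5_rem_seq) - k
  if (up_keep < 0L) return(FALSE)
  up_w <- if (strand == "+")
    paste0(substr(g, pos - up_keep + 1L, pos), site, utr5_rem_seq)
  else
    paste0(revcomp(substr(g, pos + k + 1L, pos + k + up_keep)),
           revcomp(site), utr5_rem_seq)
  hits <- 0L
  for (i in seq_len(nchar(up_w) - k + 1L)) {
    if (substr(up_w, i, i + k - 1L) == tsd_w) hits <- hits + 1L
  }
  if (hits != 1L) return(FALSE)
  after_up <- chars(substr(utr5_rem_seq, 1L, 3L))
  ext3 <- chars(substr(ext, 1L, 3L))
  j <- seq_len(min(length(after_up), length(ext3)))
  if (length(j) > 0L && any(after_up[j] == ext3[j])) return(FALSE)
  TRUE
}

# Insert one retro-copy of `parent` into `genome_str`: event parameters are
# drawn once, then insertion sites are drawn until the truth guards hold.
# Uses the ambient RNG.
insert_retrocopy <- function(genome_str, parent, config, id, avoid = NULL) {
  n <- nchar(genome_str)
  k <- sample(seq.int(config$tsd_len_range[1], config$tsd_len_range[2]), 1L)
  tail_len <- sample(seq.int(config$tail_len_range[1],
                             config$tail_len_range[2]), 1L)
  strand <- if (stats::runif(1) < config$minus_strand_prob) "-" else "+"
  mrna <- parent$mrna
  trunc_len <- 0L
  if (stats::runif(1) < config$truncation_probability) {
    trunc_len <- sample.int(parent$utr5_len + (parent$cds_end -
                                               parent$cds_start) %/% 2L, 1L)
    mrna <- substr(mrna, trunc_len + 1L, nchar(mrna))
  }
  cds_start_rem <- max(parent$cds_start - trunc_len, 1L)
  cds_end_rem <- parent$cds_end - trunc_len
  planted_stop <- NA_integer_
  if (trunc_len < parent$cds_start &&
      stats::runif(1) < config$nonsense_probability) {
    planted_stop <- sample(seq.int(2L, parent$aa_len), 1L)
    off <- cds_start_rem - 1L + 3L * (planted_stop - 1L)
    mrna <- paste0(substr(mrna, 1L, off), "TAA",
                   substr(mrna, off + 4L, nchar(mrna)))
  }
  utr5_rem_seq <- if (cds_start_rem > 1L) substr(mrna, 1L, cds_start_rem - 1L)
                  else ""
  pos <- NULL
  for (try in seq_len(500L)) {
    p <- draw_insertion_pos(n, config, avoid)
    if (site_guards_ok(genome_str, p, k, strand, utr5_rem_seq)) {
      pos <- p
      break
    }
  }
  if (is.null(pos))
    stop("placement error: no guard-satisfying insertion site found")
  unit0 <- paste0(mrna, strrep("A", tail_len))
  mut <- mutate_seq(unit0, config$copy_mutation_rate)
  unit <- mut$seq
  site <- substr(genome_str, pos + 1L, pos + k)
  seg <- if (strand == "+") unit else revcomp(unit)
  new_genome <- paste0(substr(genome_str, 1L, pos + k), seg,
                       substr(genome_str, pos + 1L, n))
  Lu <- nchar(unit)
  has_start <- trunc_len < parent$cds_start
  if (strand == "+") {
    start0 <- pos + k + cds_start_rem - 1L
    end0 <- pos + k + cds_end_rem
  } else {
    start0 <- pos + k + (Lu - cds_end_rem)
    end0 <- pos + k + (Lu - cds_start_rem + 1L)
  }
  body <- substr(unit, cds_start_rem, cds_end_rem)
  utr5_rem <- if (has_start) parent$cds_start - 1L - trunc_len else 0L
  locus <- data.frame(
    locus_id = id, species = config$species, contig = config$contig,
    start = start0, end = end0, strand = strand,
    gene_name = paste0(parent$name, "P_", id), exon_count = 1L,
    upstream_gene = NA_character_, downstream_gene = NA_character_,
    host_gene = NA_character_, stringsAsFactors = FALSE)
  truth <- list(
    locus_id = id, parent_id = parent$name, insertion_pos = pos,
    strand = strand, tsd_len = k,
    tsd_sequence = if (strand == "+") site else revcomp(site),
    utr5_rem_len = utr5_rem,
    signal_pos = parent$signal_pos, tail_start = parent$utr3_len,
    tail_len = tail_len,
    planted_mutations = mut$positions,
    premature_stop = if (has_start) {
      fs <- first_stop_index(body)
      if (!is.na(fs) && fs < parent$aa_len + 1L) fs else NA_integer_
    } else NA_integer_,
    truncated_5prime = trunc_len > 0L, trunc_len = trunc_len,
    unit_len = Lu, has_canonical_start = has_start)
  list(genome = new_genome, locus = locus, truth = truth,
       inserted_len = Lu + k)
}

#' Simulate one retrotransposition event
#'
#' Inserts a spliced copy of `parent` (5' UTR + CDS + 3' UTR + poly-A tail)
#' at a uniformly drawn background position, duplicating the target-site
#' k-mer on both flanks, with optional copy mutations, a planted premature
#' stop and 5' truncation per the configured probabilities.
#'
#' @param parent A parent gene object (element of `parent_genes` from
#'   [simulate_genome()]).
#' @param genome Genome record or string.
#' @param config A [sim_config()].
#' @param avoid Two-column matrix of 0-based half-open intervals the
#'   insertion site must not come within `insertion_buffer` of (e.g. the
#'   cluster span).
#' @param id Locus id for the new copy.
#' @param seed Optional seed; `NULL` uses the ambient RNG stream.
#' @return A list: `genome` (modified string), `locus` (new one-row loci
#'   data.frame), `truth`, `inserted_len`.
#' @export
simulate_retrotransposition <- function(parent, genome, config,
                                        avoid = NULL, id = "retro1",
                                        seed = NULL) {
  g <- as_residues(genome)
  with_seed(seed, insert_retrocopy(g, parent, config, id, avoid))
}

draw_insertion_pos <- function(n, config, avoid) {
  buf <- config$insertion_buffer
  k_max <- config$tsd_len_range[2]
  for (try in seq_len(1000L)) {
    pos <- sample.int(n - k_max - buf, 1L)
    ok <- pos > buf
    if (ok && !is.null(avoid) && nrow(avoid) > 0L) {
      ok <- all(pos + buf <= avoid[, 1] | pos - buf >= avoid[, 2])
    }
    if (ok) return(pos)
  }
  stop("placement error: no insertion site found outside occupied regions")
}

#' Simulate a full genome with retro-insertions
#'
#' Builds the canonical-cluster contig plus a background contig and applies
#' `n_insertions` sequential retrotransposition events (parents drawn
#' uniformly among the IR-family genes) to the background contig --
#' retrogenes land away from the cluster chromosome, as the scattered
#' copies do in real genomes.  Locus coordinates stay consistent as the
#' contig grows; insertions never land within `insertion_buffer` of each
#' other.
#'
#' @param config A [sim_config()].
#' @return A list of class `retro_sim`: `genome` (two-contig record
#'   data.frame), `loci` (cluster + retro loci), `parents`, `parent_genes`,
#'   `truth` (cluster truth plus one entry per insertion).
#' @export
simulate_retrogenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    base <- simulate_genome_core(config)
    g <- random_dna(config$genome_len, config$gc)   # background contig
    loci <- base$loci
    avoid <- matrix(integer(0), 0L, 2L)
    insertions <- vector("list", config$n_insertions)
    # retro-copies descend from the IR family genes, not IFITM5/IFITM10
    ir_parents <- setdiff(names(base$parent_genes), c("IFITM5", "IFITM10"))
    retro_loci <- list()
    for (i in seq_len(config$n_insertions)) {
      parent <- base$parent_genes[[sample(ir_parents, 1L)]]
      res <- insert_retrocopy(g, parent, config, paste0("retro", i), avoid)
      pos <- res$truth$insertion_pos
      g <- res$genome
      dL <- res$inserted_len
      if (length(retro_loci) > 0L) {
        for (j in seq_along(retro_loci)) {
          if (retro_loci[[j]]$start >= pos) {
            retro_loci[[j]]$start <- retro_loci[[j]]$start + dL
            retro_loci[[j]]$end <- retro_loci[[j]]$end + dL
          }
        }
      }
      avoid[avoid[, 1] >= pos, ] <- avoid[avoid[, 1] >= pos, ] + dL
      avoid <- rbind(avoid, c(pos, pos + dL))
      res$locus$contig <- config$retro_contig
      retro_loci[[i]] <- res$locus
      insertions[[i]] <- res$truth
    }
    loci <- do.call(rbind, c(list(loci), retro_loci))
    structure(list(
      genome = data.frame(id = c(config$contig, config$retro_contig),
                          description = "",
                          residues = c(base$genome$residues, g),
                          stringsAsFactors = FALSE),
      loci = loci, parents = base$parents, parent_genes = base$parent_genes,
      truth = c(base$truth, list(insertions = insertions))),
      class = "retro_sim")
  })
}

#' Simulate a two-parent chimeric sequence
#'
#' @param parent_a,parent_b Records or strings (same alphabet).
#' @param breakpoint Integer breakpoint `b` (the emitted sequence is
#'   `parent_a[1..b] + parent_b[(b+1)..]`) or `"random"`.
#' @param mutation_rate Optional per-site substitution rate applied to the
#'   emitted sequence.
#' @param seed Optional seed; `NULL` uses the ambient RNG stream.
#' @return A list: `sequence`, `truth` (parent ids and breakpoint).
#' @export
simulate_chimera <- function(parent_a, parent_b, breakpoint = "random",
                             mutation_rate = 0, seed = NULL) {
  sa <- as_residues(parent_a); sb <- as_residues(parent_b)
  with_seed(seed, {
    b <- if (identical(breakpoint, "random"))
      sample.int(min(nchar(sa), nchar(sb)) - 1L, 1L)
    else as.integer(breakpoint)
    if (b < 0L || b > min(nchar(sa), nchar(sb)))
      stop("argument error: breakpoint out of range")
    s <- paste0(substr(sa, 1L, b), substr(sb, b + 1L, nchar(sb)))
    letters <- if (infer_alphabet(s) == "dna") DNA_LETTERS else AA_LETTERS
    mut <- mutate_seq(s, mutation_rate, letters)
    list(sequence = mut$seq,
         truth = list(left_parent = record_id(parent_a, "parent_a"),
                      right_parent = record_id(parent_b, "parent_b"),
                      breakpoint = b,
                      mutated_positions = mut$positions))
  })
}

#' Evolve sequences along a known tree
#'
#' Substitution-only (no indel) evolution: on each branch the number of
#' substitution events is Poisson with mean `rate * branch length * sites`,
#' each event changing a uniformly chosen site to a different uniformly
#' chosen residue (Jukes-Cantor for DNA, equal rates for protein).  Leaves
#' come back aligned.
#'
#' @param tree An ape `phylo` with branch lengths.
#' @param root_seq Root sequence (record or string).
#' @param subst_rate Substitutions per site per unit branch length.
#' @param seed Optional seed; `NULL` uses the ambient RNG stream.
#' @return A list: `records` (aligned leaf data.frame), `msa`, `truth`
#'   (the generating tree and per-branch substitution counts).
#' @export
evolve_sequences <- function(tree, root_seq, subst_rate, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  s0 <- as_residues(root_seq)
  letters <- if (infer_alphabet(s0) == "dna") DNA_LETTERS else AA_LETTERS
  L <- nchar(s0)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- chars(s0)
    n_events <- integer(nrow(tree$edge))
    ord <- reorder(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      from <- ord$edge[e, 1L]; to <- ord$edge[e, 2L]
      cs <- seqs[[from]]
      n <- stats::rpois(1L, subst_rate * ord$edge.length[e] * L)
      n_events[e] <- n
      if (n > 0L) {
        for (i in sample.int(L, n, replace = TRUE)) {
          cs[i] <- sample(setdiff(letters, cs[i]), 1L)
        }
      }
      seqs[[to]] <- cs
    }
    records <- data.frame(
      id = tree$tip.label, description = "",
      residues = vapply(seqs[seq_len(ntip)], paste, "", collapse = ""),
      stringsAsFactors = FALSE)
    list(records = records, msa = as_msa(records),
         truth = list(tree = tree, branch_substitutions = n_events))
  })
}

#' Simulate a pair of divergent paralogs from a common ancestor
#'
#' Each parent accumulates substitutions independently at `divergence` per
#' site from a random ancestor, the way paralogous gene copies diverge.
#'
#' @param length Sequence length.
#' @param divergence Per-site substitution probability per parent.
#' @param alphabet `"protein"` or `"dna"`.
#' @param seed Optional seed; `NULL` uses the ambient RNG stream.
#' @return A list with `ancestor`, `parent_a`, `parent_b` (strings).
#' @export
simulate_parent_pair <- function(length = 130L, divergence = 0.15,
                                 alphabet = c("protein", "dna"),
                                 seed = NULL) {
  alphabet <- match.arg(alphabet)
  letters <- if (alphabet == "dna") DNA_LETTERS else AA_LETTERS
  with_seed(seed, {
    anc <- paste(sample(letters, length, replace = TRUE), collapse = "")
    list(ancestor = anc,
         parent_a = mutate_seq(anc, divergence, letters)$seq,
         parent_b = mutate_seq(anc, divergence, letters)$seq)
  })
}

#' Simulate terminus-differentiated protein group families
#'
#' Builds `n_groups` protein families sharing a conserved central domain
#' (emulating the CD225 core) but carrying group-specific N- and C-terminal
#' blocks that differ in sequence and in ungapped length.  Members are
#' drawn from the group consensus by point substitution at non-gap
#' positions.
#'
#' @param seed Integer seed.
#' @param n_groups Number of groups (default 6, labelled with the IR-IFITM
#'   group vocabulary).
#' @param members Members per group MSA.
#' @param divergence Per-site substitution probability of members from the
#'   group consensus.
#' @param n_width,core_width,c_width Alignment block widths (columns).
#' @return A list: `msas` (named list of group member `msa`s),
#'   `consensus` (named gapped consensus strings), `n_term_cols`,
#'   `c_term_cols`, and `draw(label, divergence)` for held-out members.
#' @export
simulate_group_families <- function(seed, n_groups = 6L, members = 10L,
                                    divergence = 0.1, n_width = 24L,
                                    core_width = 60L, c_width = 30L) {
  labels <- if (n_groups <= length(IR_GROUP_LABELS))
    IR_GROUP_LABELS[seq_len(n_groups)]
  else paste0("group", seq_len(n_groups))
  with_seed(seed, {
    core <- paste(sample(AA_LETTERS, core_width, replace = TRUE), collapse = "")
    gapped_block <- function(width) {
      len <- sample(seq.int(width - 6L, width), 1L)
      paste0(paste(sample(AA_LETTERS, len, replace = TRUE), collapse = ""),
             strrep("-", width - len))
    }
    consensus <- stats::setNames(vapply(labels, function(l)
      paste0(gapped_block(n_width), core, gapped_block(c_width)), ""),
      labels)
    perturb <- function(gapped, div) {
      cs <- chars(gapped)
      idx <- which(cs != "-" & stats::runif(length(cs)) < div)
      for (i in idx) cs[i] <- sample(setdiff(AA_LETTERS, cs[i]), 1L)
      paste(cs, collapse = "")
    }
    msas <- stats::setNames(lapply(labels, function(l) {
      recs <- data.frame(
        id = paste0(l, "_m", seq_len(members)), description = "",
        residues = vapply(seq_len(members), function(i)
          perturb(consensus[[l]], divergence), ""),
        stringsAsFactors = FALSE)
      as_msa(recs, "protein")
    }), labels)
    draw <- function(label, div = divergence) {
      gsub("-", "", perturb(consensus[[label]], div), fixed = TRUE)
    }
    list(msas = msas, consensus = consensus,
         n_term_cols = c(1L, n_width),
         c_term_cols = c(n_width + core_width + 1L,
                         n_width + core_width + c_width),
         draw = draw, labels = labels)
  })
}
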