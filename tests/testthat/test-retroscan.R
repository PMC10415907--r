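one_locus <- function(start, end, strand = "+", contig = "c1",
                      id = "L1") {
  data.frame(locus_id = id, species = "sp", contig = contig, start = start,
             end = end, strand = strand, gene_name = "IFITM3",
             exon_count = 1L, upstream_gene = NA, downstream_gene = NA,
             host_gene = NA, stringsAsFactors = FALSE)
}

test_that("window extraction respects strand and contig edges", {
  set.seed(21)
  g <- rand_dna(1000)
  w <- extract_window(g, one_locus(100, 220), up = 200, down = 400)
  expect_equal(w$upstream, substr(g, 1, 100))     # truncated to 100 bp
  expect_equal(w$body, substr(g, 101, 220))
  expect_equal(w$downstream, substr(g, 221, 620))

  wm <- extract_window(g, one_locus(400, 520, strand = "-"))
  expect_equal(wm$body, revcomp(substr(g, 401, 520)))
  expect_equal(wm$upstream, revcomp(substr(g, 521, 720)))
  expect_equal(wm$downstream, revcomp(substr(g, 1, 400)))

  w50 <- extract_window(g, one_locus(50, 150))
  expect_equal(nchar(w50$upstream), 50)
  expect_error(extract_window(g, one_locus(990, 1100)), "coordinate error")
})

test_that("poly-A signal finder reports the first exact hexamer", {
  w <- structure(list(downstream = "GGTTAATAAACCCGG"), class = "retro_window")
  expect_equal(find_polya_signal(w), 4L)
  w2 <- structure(list(downstream = "GGTTCCCGGGTTTT"), class = "retro_window")
  expect_true(is.na(find_polya_signal(w2)))
  w3 <- structure(list(downstream = "GGATTAAACCAATAAA"), class = "retro_window")
  expect_true(is.na(find_polya_signal(w3)) == FALSE)
  expect_equal(find_polya_signal(w3), 10L)
  expect_equal(find_polya_signal(w3, allow_attaaa = TRUE), 2L)
})

test_that("poly-A tail start obeys the signal gap and purity rules", {
  mk <- function(d) structure(list(downstream = d), class = "retro_window")
  d <- paste0("AATAAA", "GC", strrep("A", 14), "GGGG")
  expect_equal(find_polya_tail(mk(d), signal_pos = 0L), 8L)
  # no A-run within 50 bp of the signal
  d2 <- paste0("AATAAA", rand_dna_noA <- strrep("G", 60), strrep("A", 20))
  expect_true(is.na(find_polya_tail(mk(d2), signal_pos = 0L)))
  # without a signal the scan covers the whole window
  expect_equal(find_polya_tail(mk(paste0("GGGG", strrep("A", 15))),
                               signal_pos = NA), 4L)
  # purity: one interruption inside the run is tolerated
  d3 <- paste0("AATAAA", "G", strrep("A", 7), "C", strrep("A", 10))
  expect_equal(find_polya_tail(mk(d3), signal_pos = 0L), 7L)
})

test_that("TSD finder recovers a constructed direct repeat and honours bounds", {
  set.seed(22)
  tsd <- "CATTAGCA"
  up <- paste0(rand_dna(150), "GG", tsd, rand_dna(30))   # copy ends 40bp from start codon
  down <- paste0(rand_dna(80), strrep("A", 20), tsd, rand_dna(100))
  w <- structure(list(upstream = up, downstream = down),
                 class = "retro_window")
  hit <- find_tsd(w, tail_start = 80L)
  expect_false(is.null(hit))
  expect_equal(hit$sequence, tsd)
  expect_equal(hit$length, 8L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$downstream_pos, 100L)
  expect_equal(hit$upstream_pos, 152L)

  # no shared repeat near the boundaries -> no call
  w2 <- structure(list(upstream = strrep("G", 200),
                       downstream = paste0(strrep("A", 20), strrep("C", 100))),
                  class = "retro_window")
  expect_null(find_tsd(w2, tail_start = 0L))
  expect_error(find_tsd(w, tail_start = NA), "tail_start")
})

test_that("reported TSDs always satisfy the mismatch budget (re-verified)", {
  set.seed(23)
  for (r in 1:30) {
    up <- rand_dna(200)
    tsd <- rand_dna(sample(6:20, 1))
    up <- paste0(substr(up, 1, 140), tsd,
                 substr(up, 141 + nchar(tsd), 200))
    down <- paste0(rand_dna(60), strrep("A", 25), tsd, rand_dna(60))
    w <- structure(list(upstream = up, downstream = down),
                   class = "retro_window")
    hit <- find_tsd(w, tail_start = 60L)
    if (is.null(hit)) next
    u <- substr(w$upstream, hit$upstream_pos + 1,
                hit$upstream_pos + hit$length)
    d <- substr(w$downstream, hit$downstream_pos + 1,
                hit$downstream_pos + hit$length)
    mm <- sum(strsplit(u, "")[[1]] != strsplit(d, "")[[1]])
    expect_equal(mm, hit$mismatches)
    expect_lte(mm, (hit$length %/% 10) * 1)
  }
})

test_that("CDS integrity matches a codon-by-codon translation oracle", {
  expect_equal(detect_cds_integrity("ATGTAA", expected_aa_len = 5),
               list(premature_stop_codon_index = 2L, full_cds = FALSE))
  expect_equal(detect_cds_integrity("ATGAAATGA", expected_aa_len = 2),
               list(premature_stop_codon_index = NA_integer_,
                    full_cds = TRUE))
  expect_error(detect_cds_integrity("TTGAAATGA"), "no-canonical-start")

  set.seed(24)
  for (r in 1:20) {
    n_codon <- sample(10:60, 1)
    body <- paste0("ATG", rand_dna(3 * n_codon))
    got <- detect_cds_integrity(body)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(body, 1, (nchar(body) %/% 3) * 3)), no.init.codon = TRUE))
    stops <- which(strsplit(aa, "")[[1]] == "*")
    exp_idx <- if (length(stops) > 0 && stops[1] < nchar(aa)) stops[1]
               else NA_integer_
    expect_equal(got$premature_stop_codon_index, exp_idx, info = body)
    expect_equal(got$full_cds,
                 is.na(exp_idx) && length(stops) > 0 &&
                   stops[length(stops)] == nchar(aa) &&
                   nchar(body) %% 3 == 0)
  }
})

test_that("intron-loss verdicts: spliced copy yes, junction insert no", {
  sim <- simulate_genome(sim_config(seed = 25, genome_len = 60000))
  p <- sim$parent_genes[["IFITM3"]]
  exl <- p$exon_lengths
  body <- substr(p$mrna, p$cds_start, p$cds_end)
  # spliced copy of the parent (with UTR context) has lost its introns
  w <- structure(list(upstream = substr(p$mrna, 1, p$cds_start - 1),
                      body = body,
                      downstream = substr(p$mrna, p$cds_end + 1,
                                          nchar(p$mrna))),
                 class = "retro_window")
  expect_equal(assess_intron_loss(body, p$mrna, exl, window = w), "yes")
  # the parent's own genomic sequence retains its introns
  expect_equal(assess_intron_loss(p$gene_seq, p$mrna, exl), "no")
  # a 300-bp insert at an exon junction is an intron remnant
  j <- exl[1]
  with_insert <- paste0(substr(p$mrna, 1, j), rand_dna(300),
                        substr(p$mrna, j + 1, nchar(p$mrna)))
  expect_equal(assess_intron_loss(with_insert, p$mrna, exl), "no")
  expect_error(assess_intron_loss(body, p$mrna, c(10, 20)),
               "annotation error")
})

test_that("parent assignment picks the true paralog with sane tie-breaks", {
  sim <- simulate_genome(sim_config(seed = 26, genome_len = 60000))
  pset <- sim$parents
  p3 <- sim$parent_genes[["IFITM3"]]
  w <- structure(list(locus_id = "q", strand = "+",
                      upstream = paste0(rand_dna(100),
                                        substr(p3$mrna, 1, p3$cds_start - 1)),
                      body = substr(p3$mrna, p3$cds_start, p3$cds_end),
                      downstream = paste0(substr(p3$mrna, p3$cds_end + 1,
                                                 nchar(p3$mrna)),
                                          strrep("A", 30), rand_dna(100))),
                 class = "retro_window")
  pa <- assign_parent(w, pset)
  expect_equal(pa$best_parent_id, "IFITM3")
  expect_gt(pa$margin, 0)
  expect_true(pa$recency_flag)
  expect_equal(pa$identity_cds, 1.0)

  # duplicated candidate under two ids: exact tie broken lexicographically
  dup <- pset[pset$id == "IFITM3", ]
  dup2 <- dup; dup2$id <- "AAA_copy"
  pa2 <- assign_parent(w, rbind(dup, dup2))
  expect_equal(pa2$best_parent_id, "AAA_copy")
  expect_equal(pa2$margin, 0)
  expect_error(assign_parent(w, pset[0, ]), "empty candidate")
})

test_that("scan_retrogene composes the detectors verbatim", {
  sim <- simulate_retrogenome(sim_config(seed = 27, n_insertions = 4,
                                         genome_len = 150000))
  retro <- sim$loci[grepl("^retro", sim$loci$locus_id), ]
  for (i in seq_len(nrow(retro))) {
    w <- extract_window(sim$genome, retro[i, , drop = FALSE])
    rep <- scan_retrogene(w)
    expect_identical(rep$polya_signal_pos, find_polya_signal(w))
    expect_identical(rep$polya_tail_start,
                     find_polya_tail(w, find_polya_signal(w)))
    tsd <- find_tsd(w, rep$polya_tail_start)
    expect_identical(rep$tsd, tsd)
    expect_equal(rep$lacks_intron, "unknown")  # no parent context given
  }
})

test_that("simulated hallmark truth is recovered exactly without mutation", {
  sim <- simulate_retrogenome(sim_config(seed = 28, n_insertions = 25,
                                         genome_len = 400000,
                                         nonsense_probability = 0.3))
  retro <- sim$loci[grepl("^retro", sim$loci$locus_id), ]
  res <- scan_retrogenes(sim$genome, retro, parents = sim$parents)
  for (i in seq_len(nrow(retro))) {
    tr <- sim$truth$insertions[[i]]
    row <- res$report[i, ]
    expect_equal(row$polya_signal_pos, tr$signal_pos)
    expect_equal(row$polya_tail_start, tr$tail_start)
    expect_equal(row$tsd_sequence, tr$tsd_sequence)
    expect_equal(row$premature_stop_codon, tr$premature_stop)
    expect_equal(row$parent_id, tr$parent_id)
    expect_equal(row$lack_of_intron, "yes")
    expect_equal(row$verdict,
                 if (is.na(tr$premature_stop)) "retrogene"
                 else "retropseudogene")
  }
})
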