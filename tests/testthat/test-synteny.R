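make_locus <- function(locus_id, species, contig, start, end, strand = "+",
                       gene_name = "IFITM3", exon_count = 1L,
                       upstream_gene = NA, downstream_gene = NA,
                       host_gene = NA) {
  data.frame(locus_id = locus_id, species = species, contig = contig,
             start = start, end = end, strand = strand,
             gene_name = gene_name, exon_count = exon_count,
             upstream_gene = upstream_gene, downstream_gene = downstream_gene,
             host_gene = host_gene, stringsAsFactors = FALSE)
}

base_loci <- function() {
  rbind(
    make_locus("a1", "hs", "chr11", 1000, 1500, gene_name = "PGGHG"),
    make_locus("a2", "hs", "chr11", 9000, 9500, gene_name = "CTSD"),
    make_locus("f1", "hs", "chr11", 3000, 3400, gene_name = "IFITM3"),
    make_locus("f2", "hs", "chr11", 5000, 5400, gene_name = "IFITM1",
               strand = "-"),
    make_locus("f3", "hs", "chr4", 100000, 100400, gene_name = "IFITM3P1",
               upstream_gene = "EHPA5", downstream_gene = "CENPC"))
}

test_that("loci between anchors are canonical, remote loci scattered", {
  rep <- classify_loci(base_loci())
  cls <- setNames(rep$loci$class, rep$loci$locus_id)
  expect_equal(cls[["f1"]], "canonical")
  expect_equal(cls[["f2"]], "canonical")
  expect_equal(cls[["f3"]], "scattered")
  expect_true(all(rep$loci$intron_resident == FALSE))
})

test_that("a species missing one anchor still classifies by the others", {
  # cluster lacking B4GALNT4 (chromosomal rearrangement case)
  loci <- base_loci()
  expect_false(any(canon <- grepl("B4GALNT4", loci$gene_name)))
  rep <- classify_loci(loci)
  expect_equal(rep$loci$class[rep$loci$locus_id == "f1"], "canonical")
  # the alias spelling maps onto B4GALNT4
  loci2 <- rbind(loci, make_locus("a3", "hs", "chr11", 2000, 2500,
                                  gene_name = "BAGALNT4"))
  rep2 <- classify_loci(loci2)
  expect_equal(nrow(rep2$anchors), 3)
})

test_that("species without any anchors get scattered members plus a warning flag", {
  loci <- rbind(base_loci(),
                make_locus("g1", "pan", "scaf1", 100, 500,
                           gene_name = "IFITM3"))
  rep <- classify_loci(loci)
  g <- rep$loci[rep$loci$locus_id == "g1", ]
  expect_equal(g$class, "scattered")
  expect_true(g$no_anchor_warning)
})

test_that("classification partitions the family and ignores row order", {
  loci <- base_loci()
  rep1 <- classify_loci(loci)
  expect_equal(sum(rep1$loci$class == "canonical") +
                 sum(rep1$loci$class == "scattered"), 3)  # 3 family loci
  rep2 <- classify_loci(loci[sample(nrow(loci)), ])
  o1 <- rep1$loci[order(rep1$loci$locus_id), c("locus_id", "class")]
  o2 <- rep2$loci[order(rep2$loci$locus_id), c("locus_id", "class")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("shared flank groups require both flanks across >= 2 species", {
  loci <- rbind(
    make_locus("h1", "Homo sapiens", "chr12", 100, 400,
               gene_name = "IFITM3P2", upstream_gene = "AMN1",
               downstream_gene = "RESF1"),
    make_locus("p1", "Pan paniscus", "chr12", 900, 1200,
               gene_name = "IFITM3P2", upstream_gene = "AMN1",
               downstream_gene = "RESF1"),
    make_locus("u1", "Homo sapiens", "chr7", 100, 400,
               gene_name = "IFITM3P4", upstream_gene = "NUPR2",
               downstream_gene = "ZNF479"),
    make_locus("q1", "Homo sapiens", "chr2", 10, 340,
               gene_name = "IFITM3P9", upstream_gene = "PAPLOG",
               downstream_gene = "BCL11A"),
    make_locus("q2", "Pan troglodytes", "chr2a", 10, 340,
               gene_name = "IFITM3P9", upstream_gene = "PAPLOG",
               downstream_gene = "BCL11A"),
    make_locus("q3", "Gorilla gorilla", "chr2a", 10, 340,
               gene_name = "IFITM3P9", upstream_gene = "BCL11A",
               downstream_gene = "PAPLOG"))
  groups <- shared_flank_groups(loci)
  expect_length(groups, 2)
  sizes <- sort(lengths(groups))
  expect_equal(sizes, c(2L, 3L))
  # the unordered flank pair groups q3 despite swapped orientation
  expect_true(any(vapply(groups, function(g) all(c("q1", "q2", "q3") %in% g),
                         TRUE)))
  # singleton flank pair omitted
  expect_false(any(vapply(groups, function(g) "u1" %in% g, TRUE)))
})

test_that("cluster order sorts canonical members by start and keeps strand", {
  rep <- classify_loci(base_loci())
  ord <- cluster_order(rep)[["hs"]]
  expect_equal(ord$gene_name, c("IFITM3", "IFITM1"))
  expect_equal(ord$strand, c("+", "-"))
})

test_that("simulated genomes classify perfectly and recover cluster order", {
  sim <- simulate_retrogenome(sim_config(seed = 23, n_insertions = 6,
                                         genome_len = 150000))
  rep <- classify_loci(sim$loci)
  is_retro <- grepl("^retro", rep$loci$locus_id)
  expect_true(all(rep$loci$class[is_retro] == "scattered"))
  expect_true(all(rep$loci$class[!is_retro] == "canonical"))
  ord <- cluster_order(rep)[[sim$loci$species[1]]]
  cl <- sim$loci[grepl("^cluster_IFITM", sim$loci$locus_id), ]
  expect_equal(ord$gene_name, cl$gene_name[order(cl$start)])
})
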