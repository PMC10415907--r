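dna_msa <- function(seqs) {
  as_msa(data.frame(id = paste0("t", seq_along(seqs)), residues = seqs),
         "dna")
}

test_that("the coverage filter keeps exactly the >= 95% columns", {
  m3 <- dna_msa(c("AC-T", "ACGT", "ACGT"))
  f <- partial_deletion_filter(m3)
  expect_equal(f$seqs, c("ACT", "ACT", "ACT"))   # 2/3 column removed

  # 19 of 20 rows covered is exactly 0.95 -> retained
  seqs <- c("A-", rep("AA", 19))
  f20 <- partial_deletion_filter(dna_msa(seqs))
  expect_equal(nchar(f20$seqs[1]), 2L)

  clean <- dna_msa(c("ACGT", "ACGA", "ACGC"))
  expect_identical(partial_deletion_filter(clean)$seqs, clean$seqs)
  # idempotence
  expect_identical(partial_deletion_filter(f)$seqs, f$seqs)
  expect_error(partial_deletion_filter(dna_msa(c("-A", "A-", "--"))),
               "empty-alignment")
})

test_that("the coverage filter equals a brute-force column scan (with N as gap)", {
  set.seed(51)
  for (r in 1:10) {
    n <- sample(4:20, 1); L <- 40
    seqs <- vapply(seq_len(n), function(i) {
      cs <- strsplit(rand_dna(L), "")[[1]]
      cs[stats::runif(L) < 0.06] <- sample(c("-", "N"), 1)
      paste(cs, collapse = "")
    }, "")
    keep <- brute_filter_keep(seqs, 0.95)
    if (!any(keep)) next
    got <- partial_deletion_filter(dna_msa(seqs), 0.95)
    exp <- vapply(seqs, function(s)
      paste(strsplit(s, "")[[1]][keep], collapse = ""), "",
      USE.NAMES = FALSE)
    expect_identical(got$seqs, exp)
  }
})

test_that("distance models match their closed forms and flag saturation", {
  m <- dna_msa(c("AAAA", "AAAT", "TTTA"))
  dp <- distance_matrix(m, "p")
  expect_equal(dp["t1", "t2"], 0.25)
  expect_equal(dp["t1", "t1"], 0)
  expect_true(isSymmetric(unname(dp)))

  pois <- distance_matrix(m, "poisson")
  expect_equal(pois["t1", "t2"], -log(0.75), tolerance = 1e-12)
  jc <- distance_matrix(m, "jc69")
  expect_equal(jc["t1", "t2"], -0.75 * log(1 - 4 * 0.25 / 3),
               tolerance = 1e-12)
  # p = 0.75 saturates JC69
  msat <- dna_msa(c("AAAA", "TTTA", "CCGG"))
  js <- distance_matrix(msat, "jc69", max_dist = 5)
  expect_equal(js["t1", "t2"], 5)
  expect_true("t1|t2" %in% attr(js, "saturated"))
  # gaps/ambiguity excluded pairwise; an all-conflicting pair errors
  expect_error(distance_matrix(dna_msa(c("A-", "-A", "AA")), "p"),
               "zero comparable")
})

test_that("NJ recovers additive trees exactly, with the 3-taxon closed form", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(d3)
  bl <- setNames(tr3$edge.length[match(seq_len(3), tr3$edge[, 2])],
                 tr3$tip.label)
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)

  # the classic 4-taxon additive matrix
  taxa <- c("a", "b", "c", "d")
  D <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4, dimnames = list(taxa, taxa))
  tr <- nj_tree(D)
  expect_equal(phangorn::RF.dist(tr, read_newick("((a:1,b:1):1,(c:1,d:1):1);")),
               0)
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 1, 2), tolerance = 1e-9)

  set.seed(52)
  for (r in 1:10) {
    gen <- rand_tree(sample(5:10, 1), 0.1, 1)
    got <- nj_tree(cophenetic(gen))
    expect_equal(phangorn::RF.dist(ape::unroot(gen), got), 0)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
})

test_that("evolved sequences at low rate recover the generating topology", {
  set.seed(53)
  ok <- 0; n <- 15
  for (r in seq_len(n)) {
    gen <- rand_tree(8, 0.05, 0.15)
    ev <- evolve_sequences(gen, rand_dna(2000), 1)
    got <- nj_tree(distance_matrix(ev$msa, "jc69"))
    if (phangorn::RF.dist(ape::unroot(gen), got) == 0) ok <- ok + 1
  }
  expect_gte(ok / n, 0.9)
})

test_that("bootstrap supports are reproducible and bounded", {
  set.seed(54)
  gen <- rand_tree(8, 0.05, 0.2)
  ev <- evolve_sequences(gen, rand_dna(1500), 1, seed = 7)
  b1 <- bootstrap_support(ev$msa, replicates = 50, seed = 99, model = "jc69")
  b2 <- bootstrap_support(ev$msa, replicates = 50, seed = 99, model = "jc69")
  expect_identical(write_newick(b1), write_newick(b2))
  sup <- suppressWarnings(as.integer(b1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))

  bone <- bootstrap_support(ev$msa, replicates = 1, seed = 3, model = "jc69")
  expect_true(all(bone$node.label %in% c("", "0", "100")))
  expect_error(bootstrap_support(ev$msa, replicates = 0, seed = 1), "replicates")
})

test_that("bootstrap supports do not depend on taxon input order", {
  set.seed(55)
  gen <- rand_tree(6, 0.05, 0.2)
  ev <- evolve_sequences(gen, rand_dna(1200), 1, seed = 11)
  msa_a <- ev$msa
  perm <- sample(length(msa_a$ids))
  msa_b <- msa_a
  msa_b$ids <- msa_a$ids[perm]
  msa_b$seqs <- msa_a$seqs[perm]
  ba <- bootstrap_support(msa_a, replicates = 30, seed = 5, model = "jc69")
  bb <- bootstrap_support(msa_b, replicates = 30, seed = 5, model = "jc69")
  # same bipartitions with the same supports, up to relabeling
  key <- function(tr) {
    sp <- ape::prop.part(tr)
    all_tips <- sort(tr$tip.label)
    labs <- lapply(sp, function(i) {
      side <- sort(tr$tip.label[i])
      # canonicalize: represent each bipartition by the side holding the
      # alphabetically first taxon
      if (all_tips[1] %in% side) side else setdiff(all_tips, side)
    })
    sort(vapply(labs, paste, "", collapse = "|"))
  }
  expect_identical(key(ba), key(bb))
  expect_equal(phangorn::RF.dist(ba, bb), 0)
})
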