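test_that("barcode matrix tallies observations and drops uninformative barcodes", {
  reads <- toy_reads(barcode = c(1, 1, 1, 2),
                     snp = c(1, 1, 2, 3),
                     allele = c(1, 1, 0, 1), n_snps = 3)
  m <- build_barcode_matrix(reads)
  expect_equal(nrow(m), 2) # barcode 2 (one SNP) dropped
  expect_equal(m[barcode == 1 & snp == 1, c(ref_n, alt_n)], c(0L, 2L))
  expect_equal(m[barcode == 1 & snp == 2, c(ref_n, alt_n)], c(1L, 0L))
  # hand-tallied 3 x 3 case
  reads3 <- toy_reads(barcode = c(1, 1, 2, 2, 3, 3, 3),
                      snp = c(1, 2, 2, 3, 1, 1, 3),
                      allele = c(1, 0, 0, 1, 0, 1, 1), n_snps = 3)
  m3 <- build_barcode_matrix(reads3)
  expect_equal(nrow(m3), 6)
  expect_equal(m3[barcode == 3 & snp == 1, c(ref_n, alt_n)], c(1L, 1L))
  # empty in, empty out
  expect_equal(nrow(build_barcode_matrix(toy_reads(integer(), integer(),
                                                   integer(), n_snps = 2))), 0)
})

test_that("phase graph votes cis/trans from per-barcode majorities, ties discarded", {
  # b1: SNP1=alt, SNP2=alt -> one cis vote
  g1 <- build_phase_graph(build_barcode_matrix(
    toy_reads(c(1, 1), c(1, 2), c(1, 1))))
  expect_equal(g1[i == 1 & j == 2, c(cis, trans)], c(1L, 0L))
  # b1 alt/ref + b2 ref/alt -> two trans votes
  g2 <- build_phase_graph(build_barcode_matrix(
    toy_reads(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 0, 0, 1))))
  expect_equal(g2[i == 1 & j == 2, c(cis, trans)], c(0L, 2L))
  # a tie at SNP1 removes that SNP from the barcode's pairs
  g3 <- build_phase_graph(build_barcode_matrix(
    toy_reads(c(1, 1, 1, 1), c(1, 1, 2, 3), c(0, 1, 1, 1))))
  expect_equal(nrow(g3[i == 1 | j == 1]), 0)
  expect_equal(g3[i == 2 & j == 3, c(cis, trans)], c(1L, 0L))
})

test_that("block calling keeps supported edges, splits components, drops noisy edges", {
  # chain 1-2-3, all cis with support 5: one block, same strand
  bc <- rep(1:5, each = 3)
  reads <- toy_reads(bc, rep(1:3, 5), rep(1, 15))
  b <- call_phase_blocks(build_phase_graph(build_barcode_matrix(reads)))
  expect_length(b$blocks, 1)
  expect_equal(b$blocks[[1]]$snps, 1:3)
  expect_equal(diff(range(b$blocks[[1]]$phase01)), 0)
  # two components -> two blocks
  reads2 <- toy_reads(c(1, 1, 2, 2, 3, 3, 4, 4),
                      c(1, 2, 1, 2, 4, 5, 4, 5),
                      c(1, 1, 1, 1, 0, 1, 0, 1), n_snps = 5)
  b2 <- call_phase_blocks(build_phase_graph(build_barcode_matrix(reads2)))
  expect_length(b2$blocks, 2)
  expect_equal(lapply(b2$blocks, `[[`, "snps"), list(1:2, 4:5))
  # noisy edge: cis 5 / trans 4 has ratio 0.56 < 0.75 and is dropped
  g <- data.table::data.table(i = 1L, j = 2L, cis = 5L, trans = 4L)
  data.table::setattr(g, "n_snps", 2L)
  data.table::setattr(g, "class", class(build_phase_graph(build_barcode_matrix(reads))))
  b3 <- call_phase_blocks(g)
  expect_length(b3$blocks, 0)
  expect_error(call_phase_blocks(g, min_ratio = 0.4), "min_ratio")
})

test_that("raising min_support never merges blocks", {
  set.seed(71)
  for (rep in 1:5) {
    n_snps <- 8
    bcs <- 12
    barcode <- rep(seq_len(bcs), each = 3)
    snp <- unlist(lapply(seq_len(bcs), function(b) sort(sample(n_snps, 3))))
    truth <- rbinom(n_snps, 1, 0.5)
    side <- rep(rbinom(bcs, 1, 0.5), each = 3)
    allele <- ifelse(side == 1, truth[snp], 1 - truth[snp])
    allele <- as.integer(xor(allele, rbinom(length(allele), 1, 0.1)))
    g <- build_phase_graph(build_barcode_matrix(
      toy_reads(barcode, snp, allele, n_snps = n_snps)))
    lo <- call_phase_blocks(g, min_support = 1)
    hi <- call_phase_blocks(g, min_support = 2)
    blk_lo <- rep(NA_integer_, n_snps)
    for (k in seq_along(lo$blocks)) blk_lo[lo$blocks[[k]]$snps] <- k
    for (bk in hi$blocks) { # every high-support block sits inside one low block
      expect_equal(length(unique(blk_lo[bk$snps])), 1)
    }
  }
})

test_that("block phasing attains the exhaustive maximum-agreement optimum", {
  set.seed(72)
  for (rep in 1:25) {
    n_snps <- sample(4:10, 1)
    bcs <- sample(6:15, 1)
    k_obs <- 3
    barcode <- rep(seq_len(bcs), each = k_obs)
    snp <- unlist(lapply(seq_len(bcs), function(b) sort(sample(n_snps, k_obs))))
    truth <- rbinom(n_snps, 1, 0.5)
    side <- rep(rbinom(bcs, 1, 0.5), each = k_obs)
    allele <- ifelse(side == 1, truth[snp], 1 - truth[snp])
    allele <- as.integer(xor(allele, rbinom(length(allele), 1, 0.05)))
    g <- build_phase_graph(build_barcode_matrix(
      toy_reads(barcode, snp, allele, n_snps = n_snps)))
    b <- call_phase_blocks(g, min_support = 1, min_ratio = 0.51)
    win <- pmax(g$cis, g$trans)
    keep <- win >= 1 & win / (g$cis + g$trans) >= 0.51
    ei <- g$i[keep]; ej <- g$j[keep]
    cis <- g$cis[keep]; trans <- g$trans[keep]
    for (bk in b$blocks) {
      inb <- ei %in% bk$snps
      r <- bk$phase01
      names(r) <- as.character(bk$snps)
      got <- phasing_score(r, ei[inb], ej[inb], cis[inb], trans[inb])
      opt <- max_agreement_score(bk$snps, ei[inb], ej[inb], cis[inb], trans[inb])
      expect_equal(got, opt)
    }
  }
})

test_that("anchoring designates HapA from mutation-supporting barcodes", {
  # two barcodes define a block over SNPs 1-3; barcode 7 carries the
  # point mutation and matches strand (alt, alt, ref)
  reads <- toy_reads(barcode = c(1, 1, 1, 2, 2, 2, 7, 7),
                     snp = c(1, 2, 3, 1, 2, 3, 1, 2),
                     allele = c(1, 1, 0, 0, 0, 1, 1, 1),
                     mutation_obs = data.frame(barcode = 7L, allele = 1L))
  mut <- sv_mutation("point", 1500)
  pair <- phase_linked_reads(reads, mut, min_support = 1, min_ratio = 0.6)
  expect_equal(pair$hapA[1:3], c(1L, 1L, 0L))
  expect_equal(pair$hapB[1:3], c(0L, 0L, 1L))
  expect_true(all(pair$hapA != pair$hapB, na.rm = TRUE)) # complementarity
  # zero mutation-supporting barcodes is not linkable
  reads0 <- toy_reads(c(1, 1), c(1, 2), c(1, 1))
  expect_error(phase_linked_reads(reads0, mut, min_support = 1),
               "not linkable")
})

test_that("unanchored blocks chain through shared barcodes; labels flip with alleles", {
  # block A (SNPs 1-2) holds the mutation signal; block B (SNPs 4-5) is
  # only reachable through barcodes 31-33 spanning both blocks
  barcode <- c(1, 1, 2, 2, 11, 11, 12, 12, 31, 31, 32, 32, 33, 33)
  snp <- c(1, 2, 1, 2, 4, 5, 4, 5, 2, 4, 2, 4, 2, 4)
  allele <- c(1, 1, 1, 1, 0, 1, 0, 1, 1, 0, 1, 0, 1, 0)
  mo <- data.frame(barcode = c(1L, 2L), allele = c(1L, 1L))
  reads <- toy_reads(barcode, snp, allele, n_snps = 5, mutation_obs = mo)
  mut <- sv_mutation("point", 500)
  pair <- phase_linked_reads(reads, mut, min_support = 1, min_ratio = 0.6)
  expect_equal(pair$hapA, c(1L, 1L, NA, 0L, 1L))
  # flipping every observation allele flips HapA/HapB exactly
  flipped <- reads
  flipped$observations$allele <- 1L - flipped$observations$allele
  pair_f <- phase_linked_reads(flipped, mut, min_support = 1, min_ratio = 0.6)
  expect_equal(pair_f$hapA, 1L - pair$hapA)
  # permuting barcode ids changes nothing
  relab <- reads
  map <- c(31, 1, 12, 33, 2, 11, 32)
  ids <- c(1, 2, 11, 12, 31, 32, 33)
  relab$observations$barcode <- map[match(relab$observations$barcode, ids)]
  relab$mutation_obs$barcode <- map[match(relab$mutation_obs$barcode, ids)]
  pair_r <- phase_linked_reads(relab, mut, min_support = 1, min_ratio = 0.6)
  expect_equal(pair_r$hapA, pair$hapA)
})

test_that("error-free linked reads recover the diplotype exactly across seeds", {
  for (s in c(21, 22, 23)) {
    dip <- simulate_diplotype(small_region(), sv_mutation("point", 31300000),
                              seed = s)
    reads <- simulate_linked_reads(dip, small_params(seed = s + 100))
    pair <- phase_linked_reads(reads, dip$mutation)
    pc <- phasing_concordance(pair, truth_hapA(dip))
    expect_equal(pc$concordance, 1)
    expect_equal(pc$switch_errors, 0)
    expect_gt(pc$n_phased / nrow(dip$snps), 0.99)
  }
})

test_that("N50 follows the sorted-cumulative definition", {
  expect_equal(n50_phase_block(c(10, 20, 30, 40) * 1e3), 30e3)
  expect_equal(n50_phase_block(42.7e3), 42.7e3)
  expect_equal(n50_phase_block(rep(5e3, 7)), 5e3)
  expect_error(n50_phase_block(numeric()), "no blocks")
})

test_that("concordance and switch errors are counted against truth", {
  hapA <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L)
  pair <- structure(list(hapA = hapA, hapB = 1L - hapA,
                         unphased_snps = integer(), anchor_evidence = 1L,
                         pos = seq_along(hapA) * 1000, blocks = NULL,
                         anchored = 1L, mutation = NULL),
                    class = "haplotype_pair")
  same <- phasing_concordance(pair, hapA)
  expect_equal(same$concordance, 1)
  expect_equal(same$switch_errors, 0)
  comp <- phasing_concordance(pair, 1L - hapA)
  expect_equal(comp$concordance, 0)
  expect_equal(comp$switch_errors, 0)
  # strand flip halfway: half concordant, one switch
  flip <- c(hapA[1:5], 1L - hapA[6:10])
  half <- phasing_concordance(pair, flip)
  expect_equal(half$concordance, 0.5)
  expect_equal(half$switch_errors, 1)
  expect_error(phasing_concordance(pair, rep(NA_integer_, 10)), "no phased SNP")
})
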