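# Independent oracles and fixture builders used across the suite.

# Exhaustive optimal-partitioning segmentation (no pruning): the oracle
# for PELT. Same cost and penalty, O(n^2) dynamic program over every
# admissible last-changepoint position.
dp_segment_oracle <- function(x, sigma2, beta, min_seg) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  C <- function(s, t) {
    l <- t - s
    ((cs2[t + 1] - cs2[s + 1]) - (cs[t + 1] - cs[s + 1])^2 / l) / sigma2 + log(l)
  }
  FF <- rep(Inf, n + 1)
  FF[1] <- -beta
  last <- integer(n + 1)
  for (t in seq_len(n)) {
    ss <- 0:(t - 1)
    ss <- ss[t - ss >= min_seg & (ss == 0L | ss >= min_seg)]
    if (!length(ss)) next
    v <- vapply(ss, function(s) FF[s + 1] + C(s, t) + beta, 1)
    FF[t + 1] <- min(v)
    last[t + 1] <- ss[which.min(v)]
  }
  cp <- integer()
  t <- n
  while (t > 0) {
    s <- last[t + 1]
    if (s == 0) break
    cp <- c(s, cp)
    t <- s
  }
  cp
}

# Exhaustive maximum-agreement phasing over the kept edges of a small
# graph: enumerates every strand assignment of the component's SNPs and
# maximises the number of satisfied edge votes (cis votes satisfied by
# equal strands, trans by opposite). Returns the maximum achievable
# agreement score for a component.
max_agreement_score <- function(snps, ei, ej, cis, trans) {
  k <- length(snps)
  best <- -Inf
  for (mask in 0:(2^(k - 1) - 1)) {
    r <- c(0L, as.integer(intToBits(mask))[seq_len(k - 1)])
    names(r) <- as.character(snps)
    score <- sum(ifelse(r[as.character(ei)] == r[as.character(ej)], cis, trans))
    best <- max(best, score)
  }
  best
}

# Agreement score achieved by a phase assignment r (named by SNP).
phasing_score <- function(r, ei, ej, cis, trans) {
  sum(ifelse(r[as.character(ei)] == r[as.character(ej)], cis, trans))
}

# Hand-rolled read-set builder: observations as (barcode, snp, allele)
# triples, positions defaulting to 1 kb spacing.
toy_reads <- function(barcode, snp, allele, n_snps = max(snp),
                      pos = NULL, mutation_obs = NULL,
                      params = sim_params()) {
  structure(list(
    observations = data.frame(barcode = as.integer(barcode),
                              snp = as.integer(snp),
                              allele = as.integer(allele)),
    mutation_obs = mutation_obs %||%
      data.frame(barcode = integer(), allele = integer()),
    molecule_truth = NULL,
    snp_pos = pos %||% (seq_len(n_snps) * 1000),
    params = params), class = "barcoded_read_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A haplotype_pair built directly from a simulated diplotype's truth
# (HapA = the mutation haplotype), bypassing phasing.
ideal_pair <- function(diplotype) {
  hapA <- truth_hapA(diplotype)
  structure(list(hapA = hapA, hapB = 1L - hapA, unphased_snps = integer(),
                 anchor_evidence = 1L, pos = diplotype$snps$pos,
                 blocks = NULL, anchored = 1L,
                 mutation = diplotype$mutation),
            class = "haplotype_pair")
}

# A fraction_series built from raw (a, b) count vectors.
toy_series <- function(a, b, pos = NULL) {
  hapdose:::new_fraction_series(pos %||% (seq_along(a) * 1000),
                                as.numeric(a), as.numeric(b))
}

# Scaled-down simulation regime for fast properties: 800 kb, 200 SNPs,
# lighter molecule and read coverage, 3 molecules per gem so the
# gem-span-to-region ratio (~20%) matches the full-size regime.
small_region <- function(n_snps = 200) region_spec("chrX", 31100000, 31900000, n_snps)
small_params <- function(seed = 1L, seq_error_rate = 0) {
  sim_params(molecule_coverage = 120, target_coverage = 150,
             molecules_per_gem = 3, seq_error_rate = seq_error_rate,
             seed = seed)
}
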