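test_that("fraction series maps depths onto HapA and obeys label symmetry", {
  hapA <- c(0L, 1L, 0L)
  pair <- structure(list(hapA = hapA, hapB = 1L - hapA,
                         unphased_snps = integer(), anchor_evidence = 1L,
                         pos = c(1000, 2000, 3000), blocks = NULL,
                         anchored = 1L, mutation = NULL),
                    class = "haplotype_pair")
  counts <- data.frame(pos = c(1000, 2000, 3000),
                       ref_count = c(6L, 4L, 0L), alt_count = c(4L, 6L, 0L))
  s <- fraction_series(counts, pair)
  expect_equal(s$f, c(0.6, 0.6)) # zero-depth SNP dropped
  expect_equal(s$a, c(6, 6))
  # swapping HapA/HapB mirrors every fraction
  swapped <- pair
  swapped$hapA <- pair$hapB; swapped$hapB <- pair$hapA
  expect_equal(fraction_series(counts, swapped)$f, 1 - s$f)
  # exclusion drops SV-interior SNPs
  excl <- fraction_series(counts, pair, exclude = sv_mutation("deletion", 1500, 2500))
  expect_equal(excl$pos, 1000)
  expect_error(fraction_series(data.frame(pos = 9, ref_count = 1, alt_count = 1),
                               pair), "no plasma SNP")
})

test_that("simulated plasma fractions match the mixture-accounting oracle", {
  dip <- simulate_diplotype(region_spec(n_snps = 850),
                            sv_mutation("point", 31300000), seed = 50)
  pair <- ideal_pair(dip)
  f <- 0.0925
  counts <- simulate_plasma(dip, plasma_spec(f, transmitted_hap = dip$mutation_hap),
                            seed = 51)
  s <- fraction_series(counts, pair)
  p_oracle <- 0.5 + (f / (2 - f)) / 2
  se <- sqrt(p_oracle * (1 - p_oracle) / (200 * 850))
  expect_lt(abs(mean(s$f) - p_oracle), 3 * se)
})

test_that("the individuals-chart screen masks gross outliers once", {
  set.seed(52)
  f <- c(rnorm(100, 0.52, 0.02), 0.95)
  s <- toy_series(round(f * 200), 200 - round(f * 200))
  scr <- remove_outliers(s)
  expect_false(scr$retained[101])
  expect_true(all(scr$retained[1:100]))
  # constant series: sd 0, nothing masked
  cs <- toy_series(rep(100, 20), rep(100, 20))
  expect_true(all(remove_outliers(cs)$retained))
  # infinite limit: untouched
  expect_identical(remove_outliers(s, n_sigma = Inf), s)
  short <- toy_series(rep(100, 5), rep(100, 5))
  expect_error(remove_outliers(short), ">= 10")
})

test_that("changepoint detection finds clean shifts exactly and nothing in noise", {
  set.seed(53)
  x <- c(rnorm(50, 0.52, 0.005), rnorm(50, 0.48, 0.005))
  s <- toy_series(round(x * 1000), 1000 - round(x * 1000))
  s$f <- x # exact fractions, counts only carry depth
  cp <- detect_changepoints(s)
  expect_equal(cp$breakpoints, 50L)
  expect_equal(cp$seg_means, c(mean(x[1:50]), mean(x[51:100])), tolerance = 1e-12)
  # constant series
  flat <- toy_series(rep(104, 60), rep(96, 60))
  expect_length(detect_changepoints(flat)$breakpoints, 0)
  expect_error(detect_changepoints(toy_series(rep(1, 5), rep(1, 5))),
               "retained points")
})

test_that("PELT equals exhaustive optimal partitioning on series up to n = 200", {
  set.seed(54)
  for (r in 1:40) {
    n <- sample(25:200, 1)
    ncp <- sample(0:3, 1)
    mu <- cumsum(c(0.5, rnorm(ncp, 0, 0.03)))
    bounds <- if (ncp) sort(sample(12:(n - 12), ncp)) else integer()
    seg <- findInterval(seq_len(n), bounds + 0.5) + 1
    x <- rnorm(n, mu[seg], 0.02)
    s2 <- mean(diff(x)^2) / 2
    expect_identical(hapdose:::pelt_meanshift(x, s2, 2 * log(n), 10L),
                     dp_segment_oracle(x, s2, 2 * log(n), 10L))
  }
})

test_that("recombination is confirmed only across 0.5 with significant counts", {
  set.seed(55)
  depth <- 5000L # deep counts make the z-test decisive
  mk <- function(means) {
    f <- unlist(lapply(means, function(m) rnorm(60, m, 0.004)))
    toy_series(round(f * depth), depth - round(f * depth))
  }
  # opposite sides: flip the far segment, adjusted series level
  s <- mk(c(0.524, 0.476))
  cp <- detect_changepoints(s)
  adj <- adjust_recombination(s, cp)
  expect_true(adj$recombination)
  expect_equal(length(adj$breakpoint_pos), 1)
  expect_lt(abs(mean(adj$series$f) - 0.524), 0.003)
  # same side of 0.5: drift, not recombination
  s2 <- mk(c(0.53, 0.51))
  adj2 <- adjust_recombination(s2, detect_changepoints(s2))
  expect_false(adj2$recombination)
  expect_identical(adj2$series$f, s2$f)
  # two confirmed breakpoints: middle segment reflected once
  s3 <- mk(c(0.52, 0.48, 0.52))
  cp3 <- detect_changepoints(s3)
  adj3 <- adjust_recombination(s3, cp3)
  expect_true(adj3$recombination)
  expect_equal(length(adj3$breakpoint_pos), 2)
  expect_true(all(tapply(adj3$series$f, findInterval(adj3$series$pos,
                                                     adj3$breakpoint_pos),
                         mean) > 0.5))
  # idempotence: re-running on the adjusted series changes nothing
  cp_again <- detect_changepoints(adj3$series)
  adj_again <- adjust_recombination(adj3$series, cp_again)
  expect_identical(adj_again$series$f, adj3$series$f)
  expect_false(adj_again$recombination)
})

test_that("the unreflected segment follows the mutation locus", {
  set.seed(56)
  depth <- 5000L
  f <- c(rnorm(60, 0.524, 0.004), rnorm(60, 0.476, 0.004))
  s <- toy_series(round(f * depth), depth - round(f * depth))
  cp <- detect_changepoints(s)
  left <- adjust_recombination(s, cp, anchor_pos = s$pos[10])
  right <- adjust_recombination(s, cp, anchor_pos = s$pos[110])
  expect_gt(mean(left$series$f), 0.5) # mutation left: mutant-side level
  expect_lt(mean(right$series$f), 0.5) # mutation right: wild-type level
  expect_equal(left$series$f, 1 - right$series$f)
})

test_that("the pooled dosage call matches the binomial tail oracle", {
  s <- toy_series(9000, 8000)
  out <- call_fetal_genotype(s)
  expect_equal(out$call, "mutant_inherited")
  expect_equal(out$mean_fraction, 9000 / 17000)
  # independent tail oracle
  p_oracle <- 2 * pbinom(8000, 17000, 0.5)
  expect_equal(out$p_value, p_oracle, tolerance = 1e-6)
  expect_lt(out$p_value, 1e-10)
  bal <- call_fetal_genotype(toy_series(c(50, 50), c(50, 50)))
  expect_equal(bal$call, "inconclusive")
  expect_equal(bal$p_value, 1)
  zero <- toy_series(c(1, 1), c(1, 1))
  zero$retained <- c(FALSE, FALSE)
  expect_error(call_fetal_genotype(zero), "zero pooled depth")
})

test_that("fetal fraction inverts the X-dosage mixture", {
  expect_equal(estimate_fetal_fraction(toy_series(100, 100), n_boot = 0)$estimate, 0)
  # pure fetal signal boundary: phi = 1 -> f = 1
  pure <- estimate_fetal_fraction(toy_series(200, 0), n_boot = 0)
  expect_equal(pure$phi, 1)
  expect_equal(pure$estimate, 1)
  # recovery at the lowest printed concentration: mean of 20 seeds
  dip <- simulate_diplotype(region_spec(n_snps = 850),
                            sv_mutation("point", 31300000), seed = 57)
  pair <- ideal_pair(dip)
  ests <- vapply(1:20, function(k) {
    cc <- simulate_plasma(dip, plasma_spec(0.041, transmitted_hap = 1L),
                          seed = 600 + k)
    estimate_fetal_fraction(remove_outliers(fraction_series(cc, pair)),
                            n_boot = 0)$estimate
  }, 1)
  expect_lt(abs(mean(ests) - 0.041), 0.005)
})

test_that("relabeling HapA/HapB flips the call but not the estimates", {
  dip <- simulate_diplotype(region_spec(n_snps = 850),
                            sv_mutation("point", 31300000), seed = 58)
  pair <- ideal_pair(dip)
  flipped <- pair
  flipped$hapA <- pair$hapB; flipped$hapB <- pair$hapA
  # one draw without and one with a recombination event
  for (bp in list(integer(), 425L)) {
    cc <- simulate_plasma(dip, plasma_spec(0.06, transmitted_hap = dip$mutation_hap,
                                           recomb_breakpoints = bp), seed = 59)
    fit <- rhdo(cc, pair, n_boot = 0)
    fit_f <- rhdo(cc, flipped, n_boot = 0)
    expect_equal(fit$call, "mutant_inherited")
    expect_equal(fit_f$call, "wildtype_inherited")
    expect_equal(fit_f$mean_fraction, 1 - fit$mean_fraction, tolerance = 1e-12)
    expect_equal(fit_f$fetal_fraction, fit$fetal_fraction, tolerance = 1e-12)
    expect_equal(fit_f$recomb_breakpoints, fit$recomb_breakpoints)
    expect_equal(fit$recombination_detected, length(bp) > 0)
  }
})

test_that("rhdo reports a complete, printable object", {
  dip <- simulate_diplotype(region_spec(n_snps = 850),
                            sv_mutation("point", 31300000), seed = 60)
  cc <- simulate_plasma(dip, plasma_spec(0.0624, transmitted_hap = dip$mutation_hap),
                        seed = 61)
  fit <- rhdo(cc, ideal_pair(dip))
  expect_s3_class(fit, "rhdo")
  expect_equal(fit$call, "mutant_inherited")
  expect_gt(fit$mean_fraction, 0.5) # call invariant
  expect_equal(fit$qc$n_snps, 850)
  expect_equal(fit$qc$mean_depth, 200)
  expect_true(fit$fetal_fraction_ci[1] <= fit$fetal_fraction &&
                fit$fetal_fraction <= fit$fetal_fraction_ci[2])
  expect_named(coef(fit), c("hapA_fraction", "fetal_fraction"))
  expect_output(print(fit), "mutant_inherited")
  expect_output(print(summary(fit)), "fetal fraction")
})
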