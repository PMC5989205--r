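#' HapA read-fraction series from plasma allelic depths
#'
#' Maps the plasma REF/ALT depths onto the anchored haplotypes: at each
#' phased SNP, \code{a} is the depth of the HapA (mutant-linked) allele
#' and \code{b} of the HapB allele, and \code{f = a/(a+b)} is the HapA
#' read fraction. Unphased SNPs and SNPs with zero depth are dropped.
#'
#' @param counts a \code{plasma_counts} data.frame (columns \code{pos},
#'   \code{ref_count}, \code{alt_count}).
#' @param pair a \code{haplotype_pair}.
#' @param exclude optional \code{\link{sv_mutation}} (or list of them):
#'   SNPs inside these intervals are dropped. Sites inside a carrier
#'   deletion are hemizygous, and inside a duplication copy-imbalanced,
#'   so they are not informative heterozygous sites for dosage.
#' @return a \code{fraction_series}: list with \code{pos}, \code{a},
#'   \code{b}, \code{f} and logical \code{retained} (all TRUE here;
#'   updated by the outlier screen).
#' @export
fraction_series <- function(counts, pair, exclude = NULL) {
  stopifnot(inherits(pair, "haplotype_pair"),
            all(c("pos", "ref_count", "alt_count") %in% names(counts)))
  idx <- match(counts$pos, pair$pos)
  ok <- !is.na(idx) & !is.na(pair$hapA[ifelse(is.na(idx), 1L, idx)])
  if (!is.null(exclude)) {
    if (inherits(exclude, "sv_mutation")) exclude <- list(exclude)
    for (iv in exclude) {
      ok <- ok & !(counts$pos >= iv$start & counts$pos < iv$end)
    }
  }
  if (!any(ok)) stop_hapdose("fraction_series: no plasma SNP overlaps the phased SNPs")
  idx <- idx[ok]
  hapA <- pair$hapA[idx]
  a <- ifelse(hapA == 0L, counts$ref_count[ok], counts$alt_count[ok])
  b <- ifelse(hapA == 0L, counts$alt_count[ok], counts$ref_count[ok])
  nz <- (a + b) > 0
  a <- a[nz]; b <- b[nz]
  pos <- counts$pos[ok][nz]
  o <- order(pos)
  new_fraction_series(pos[o], a[o], b[o])
}

new_fraction_series <- function(pos, a, b, retained = NULL) {
  structure(list(pos = pos, a = a, b = b, f = a / (a + b),
                 retained = retained %||% rep(TRUE, length(pos))),
            class = "fraction_series")
}

#' @export
print.fraction_series <- function(x, ...) {
  cat(sprintf("<fraction_series> %d SNPs (%d retained), mean HapA fraction %.4f\n",
              length(x$pos), sum(x$retained),
              mean(x$f[x$retained])))
  invisible(x)
}

#' Screen outlier fractions (Shewhart individuals chart)
#'
#' Masks points whose fraction deviates from the retained-set mean by
#' more than \code{n_sigma} standard deviations, in a single pass with
#' mean and sd computed on the input retained set. This removes the
#' aberrant fractions that duplicated, deleted or repetitive sequence
#' produces before changepoint detection. A constant series (sd = 0)
#' masks nothing.
#'
#' @param series a \code{fraction_series} with at least 10 retained
#'   points.
#' @param n_sigma control-limit multiplier (default 3).
#' @return the series with its \code{retained} mask updated.
#' @export
remove_outliers <- function(series, n_sigma = 3) {
  stopifnot(inherits(series, "fraction_series"))
  idx <- which(series$retained)
  if (length(idx) < 10L) {
    stop_hapdose("remove_outliers: needs >= 10 retained points, got %d", length(idx))
  }
  if (is.infinite(n_sigma)) return(series)
  m <- mean(series$f[idx])
  s <- sd(series$f[idx])
  if (s > 0) {
    out <- abs(series$f[idx] - m) > n_sigma * s
    series$retained[idx[out]] <- FALSE
  }
  series
}

# --- changepoint detection ------------------------------------------------

# Segment cost on standardized data under a change-in-mean normal model,
# plus the modified-BIC log(length) term: C(x[s..t]) =
# (sum x^2 - (sum x)^2 / l) / sigma2 + log(l).
# cs, cs2 are cumsum(x), cumsum(x^2) with a leading 0.
.seg_cost <- function(cs, cs2, s, t, sigma2) {
  l <- t - s
  ss <- (cs2[t + 1L] - cs2[s + 1L]) - (cs[t + 1L] - cs[s + 1L])^2 / l
  ss / sigma2 + log(l)
}

#' Detect mean changepoints in the fraction series (PELT)
#'
#' Optimal change-in-mean segmentation of the retained fractions by the
#' PELT algorithm under a normal cost with a modified-BIC penalty: each
#' segment costs its standardized residual sum of squares plus
#' \code{log(segment length)}, and each changepoint adds
#' \code{2 log(n)}. The noise variance is estimated from mean squared
#' successive differences (robust to mean shifts). Zero breakpoints is a
#' legal result; segments shorter than \code{min_seg} are never
#' produced.
#'
#' @param series a \code{fraction_series}; needs at least
#'   \code{2 * min_seg} retained points.
#' @param penalty penalty name; only \code{"MBIC"} is implemented.
#' @param min_seg minimum segment length in SNPs (default 10, to
#'   suppress spurious short segments).
#' @return a \code{changepoints} object: list with \code{breakpoints}
#'   (indices into the retained subseries: value k splits between
#'   retained points k and k+1), \code{breakpoint_pos} (bp midpoints),
#'   \code{seg_means}, \code{seg_sizes}, \code{penalty_value} and
#'   \code{retained_idx}.
#' @export
detect_changepoints <- function(series, penalty = "MBIC", min_seg = 10L) {
  stopifnot(inherits(series, "fraction_series"))
  penalty <- match.arg(penalty, "MBIC")
  ridx <- which(series$retained)
  n <- length(ridx)
  if (n < 2L * min_seg) {
    stop_hapdose("detect_changepoints: needs >= %d retained points, got %d",
                 2L * min_seg, n)
  }
  x <- series$f[ridx]
  sigma2 <- mean(diff(x)^2) / 2
  if (sigma2 == 0) {
    cp <- integer()
  } else {
    cp <- pelt_meanshift(x, sigma2, beta = 2 * log(n), min_seg = min_seg)
  }
  segs <- c(0L, cp, n)
  seg_means <- vapply(seq_len(length(segs) - 1L), function(k) {
    mean(x[(segs[k] + 1L):segs[k + 1L]])
  }, 1)
  bp_pos <- if (length(cp)) {
    (series$pos[ridx[cp]] + series$pos[ridx[cp + 1L]]) / 2
  } else numeric()
  structure(list(breakpoints = cp, breakpoint_pos = bp_pos,
                 seg_means = seg_means, seg_sizes = diff(segs),
                 penalty = penalty, penalty_value = 2 * log(n),
                 sigma2 = sigma2, retained_idx = ridx),
            class = "changepoints")
}

# PELT for change in mean, normal cost with MBIC log-length term.
# Returns the changepoint index vector (possibly empty); index k means a
# split between x[k] and x[k+1].
pelt_meanshift <- function(x, sigma2, beta, min_seg) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  FF <- rep(Inf, n + 1L)   # FF[t+1] = optimal cost of x[1..t]
  FF[1L] <- -beta
  last <- integer(n + 1L)  # last changepoint before t
  cand <- 0L               # candidate previous-changepoint set
  # pruning constant: K must satisfy C(A) + C(B) + K <= C(A u B); the
  # quadratic part is superadditive but the log-length term gives
  # log(l_AB / (l_A * l_B)) >= log(4 / n), so K = log(4/n) (negative)
  K <- log(4 / max(n, 4))
  for (t in seq_len(n)) {
    eligible <- cand[t - cand >= min_seg]
    waiting <- cand[t - cand < min_seg]
    if (length(eligible)) {
      seg <- .seg_cost(cs, cs2, eligible, t, sigma2)
      costs <- FF[eligible + 1L] + seg + beta
      best <- which.min(costs)
      FF[t + 1L] <- costs[best]
      last[t + 1L] <- eligible[best]
      # prune candidates that can never be optimal again
      eligible <- eligible[FF[eligible + 1L] + seg + K <= FF[t + 1L]]
    }
    cand <- c(waiting, eligible,
              if (is.finite(FF[t + 1L])) t else integer())
  }
  cp <- integer()
  t <- n
  while (t > 0L) {
    s <- last[t + 1L]
    if (s == 0L) break
    cp <- c(s, cp)
    t <- s
  }
  cp
}

#' @export
print.changepoints <- function(x, ...) {
  cat(sprintf("<changepoints> %d breakpoint(s); segment means: %s\n",
              length(x$breakpoints),
              paste(sprintf("%.4f", x$seg_means), collapse = ", ")))
  invisible(x)
}

# two-sample z-test on pooled binomial counts; returns the p-value
.pooled_ztest <- function(a1, b1, a2, b2) {
  n1 <- a1 + b1; n2 <- a2 + b2
  p1 <- a1 / n1; p2 <- a2 / n2
  p <- (a1 + a2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  if (se == 0) return(1)
  2 * pnorm(-abs(p1 - p2) / se)
}

#' Confirm recombination breakpoints and reflect the series
#'
#' A detected breakpoint is accepted as a fetal recombination iff the
#' two flanking segment means lie on opposite sides of 0.5 \emph{and} a
#' two-sample z-test on the segments' pooled allelic counts rejects
#' equality at \code{alpha}; breakpoints failing either criterion are
#' treated as drift and ignored. Fractions beyond each confirmed
#' breakpoint are reflected (\code{a} and \code{b} swapped, so
#' \code{f -> 1 - f}), reconstructing a series that tracks one
#' transmitted haplotype throughout. The unreflected reference segment
#' is the one containing \code{anchor_pos} (the pathogenic mutation)
#' when given — the inheritance question is decided at the mutation
#' locus — and the first segment otherwise. The operation is
#' idempotent: a reflected series yields no further confirmable
#' breakpoints.
#'
#' @param series the \code{fraction_series} the changepoints were
#'   computed on.
#' @param cps a \code{changepoints} object.
#' @param alpha significance level of the confirmation z-test.
#' @param anchor_pos optional bp position anchoring the unreflected
#'   segment.
#' @return list with \code{series} (adjusted), \code{recombination}
#'   (flag), \code{breakpoint_pos} (confirmed, bp),
#'   \code{breakpoints} (confirmed, retained-index) and \code{tested}
#'   (per-breakpoint diagnostics).
#' @export
adjust_recombination <- function(series, cps, alpha = 0.01,
                                 anchor_pos = NULL) {
  stopifnot(inherits(series, "fraction_series"), inherits(cps, "changepoints"))
  ridx <- cps$retained_idx
  n <- length(ridx)
  segs <- c(0L, cps$breakpoints, n)
  nseg <- length(segs) - 1L
  if (nseg == 1L || !length(cps$breakpoints)) {
    return(list(series = series, recombination = FALSE,
                breakpoint_pos = numeric(), breakpoints = integer(),
                tested = list()))
  }
  seg_a <- seg_b <- numeric(nseg)
  for (k in seq_len(nseg)) {
    ii <- ridx[(segs[k] + 1L):segs[k + 1L]]
    seg_a[k] <- sum(series$a[ii]); seg_b[k] <- sum(series$b[ii])
  }
  m <- cps$seg_means
  confirmed <- logical(length(cps$breakpoints))
  tested <- vector("list", length(cps$breakpoints))
  for (k in seq_along(cps$breakpoints)) {
    opposite <- (m[k] - 0.5) * (m[k + 1L] - 0.5) < 0
    pval <- .pooled_ztest(seg_a[k], seg_b[k], seg_a[k + 1L], seg_b[k + 1L])
    confirmed[k] <- opposite && pval < alpha
    tested[[k]] <- list(breakpoint = cps$breakpoints[k],
                        pos = cps$breakpoint_pos[k],
                        mean_left = m[k], mean_right = m[k + 1L],
                        opposite = opposite, p_value = pval,
                        confirmed = confirmed[k])
  }
  if (!any(confirmed)) {
    return(list(series = series, recombination = FALSE,
                breakpoint_pos = numeric(), breakpoints = integer(),
                tested = tested))
  }
  bp_pos <- cps$breakpoint_pos[confirmed]
  # reflect by position so masked SNPs flip consistently; the anchor
  # side (mutation-containing segment, else the first segment) stays
  anchor <- anchor_pos %||% series$pos[1L]
  crossings <- vapply(series$pos, function(p) {
    sum(bp_pos > min(anchor, p) & bp_pos < max(anchor, p))
  }, 1)
  flip <- crossings %% 2 == 1
  a <- ifelse(flip, series$b, series$a)
  b <- ifelse(flip, series$a, series$b)
  adj <- new_fraction_series(series$pos, a, b, retained = series$retained)
  list(series = adj, recombination = TRUE, breakpoint_pos = bp_pos,
       breakpoints = cps$breakpoints[confirmed], tested = tested)
}

#' Pooled dosage test and fetal genotype call
#'
#' Pools the retained allelic depths, \code{A = sum(a)},
#' \code{B = sum(b)}, and applies a two-sided exact binomial test of
#' \code{A/(A+B)} against 0.5. If the imbalance is significant at
#' \code{alpha}, a pooled fraction above 0.5 calls the mutant-linked
#' haplotype (HapA) inherited and below 0.5 the wild-type haplotype;
#' otherwise the result is inconclusive.
#'
#' @param series a (recombination-adjusted) \code{fraction_series}.
#' @param alpha significance level (default 0.01).
#' @return list with \code{call} (\code{"mutant_inherited"},
#'   \code{"wildtype_inherited"} or \code{"inconclusive"}),
#'   \code{mean_fraction}, \code{p_value}, \code{A}, \code{B}.
#' @export
call_fetal_genotype <- function(series, alpha = 0.01) {
  stopifnot(inherits(series, "fraction_series"))
  A <- sum(series$a[series$retained])
  B <- sum(series$b[series$retained])
  if (A + B == 0) stop_hapdose("call_fetal_genotype: zero pooled depth")
  pval <- binom.test(A, A + B, p = 0.5)$p.value
  frac <- A / (A + B)
  call <- if (pval >= alpha) "inconclusive" else
    if (frac > 0.5) "mutant_inherited" else "wildtype_inherited"
  list(call = call, mean_fraction = frac, p_value = pval, A = A, B = B)
}

#' Estimate the fetal DNA fraction from the X-dosage imbalance
#'
#' On chrX with a male fetus the fetal read share is
#' \code{phi = f/(2 - f)}, and the pooled HapA fraction is
#' \code{(1 + phi)/2} (or its mirror). The estimator inverts this:
#' \code{phi_hat = |2 A/(A+B) - 1|}, \code{f_hat = 2 phi_hat /
#' (1 + phi_hat)}, with a bootstrap confidence interval over SNPs.
#'
#' @param series a recombination-adjusted \code{fraction_series} with
#'   positive pooled depth.
#' @param n_boot bootstrap resamples (default 200; 0 disables the CI).
#' @param conf CI level.
#' @return list with \code{estimate}, \code{phi}, \code{ci} and
#'   \code{n_snps}.
#' @export
estimate_fetal_fraction <- function(series, n_boot = 200L, conf = 0.95) {
  stopifnot(inherits(series, "fraction_series"))
  idx <- which(series$retained)
  A <- sum(series$a[idx]); B <- sum(series$b[idx])
  if (A + B == 0) stop_hapdose("estimate_fetal_fraction: zero pooled depth")
  est <- function(a, b) {
    phi <- abs(2 * sum(a) / (sum(a) + sum(b)) - 1)
    2 * phi / (1 + phi)
  }
  f_hat <- est(series$a[idx], series$b[idx])
  ci <- NULL
  if (n_boot > 0L) {
    boots <- vapply(seq_len(n_boot), function(i) {
      r <- sample(idx, length(idx), replace = TRUE)
      est(series$a[r], series$b[r])
    }, 1)
    ci <- unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  phi_hat <- abs(2 * A / (A + B) - 1)
  list(estimate = f_hat, phi = phi_hat, ci = ci, n_snps = length(idx))
}

#' Relative haplotype dosage analysis of one plasma draw
#'
#' The model-style entry point: takes plasma allelic depths and the
#' anchored maternal haplotypes, and runs the full dosage analysis —
#' HapA fraction series (SNPs inside the known deletion/duplication
#' interval are excluded — they are not informative heterozygous
#' sites), outlier screen, PELT changepoint detection, recombination
#' confirmation and adjustment, pooled binomial genotype call and
#' fetal-fraction estimate.
#'
#' @param counts a \code{plasma_counts} data.frame.
#' @param pair a \code{haplotype_pair}.
#' @param alpha significance level for both the recombination
#'   confirmation and the dosage call (default 0.01).
#' @param n_sigma outlier control-limit multiplier (default 3).
#' @param min_seg minimum changepoint segment length (default 10 SNPs).
#' @param penalty changepoint penalty (\code{"MBIC"}).
#' @param n_boot bootstrap resamples for the fetal-fraction CI.
#' @param mutation_pos bp position anchoring the recombination
#'   adjustment; defaults to the mutation start recorded in \code{pair}.
#' @return an object of class \code{rhdo}; see
#'   \code{\link{print.rhdo}}, \code{\link{summary.rhdo}},
#'   \code{\link{plot.rhdo}}.
#' @export
rhdo <- function(counts, pair, alpha = 0.01, n_sigma = 3, min_seg = 10L,
                 penalty = "MBIC", n_boot = 200L, mutation_pos = NULL) {
  mutation_pos <- mutation_pos %||% pair$mutation$start
  # a known deletion/duplication interval holds no informative het sites
  exclude <- if (!is.null(pair$mutation) &&
                 pair$mutation$kind %in% c("deletion", "duplication")) {
    pair$mutation
  }
  raw <- fraction_series(counts, pair, exclude = exclude)
  screened <- remove_outliers(raw, n_sigma = n_sigma)
  cps <- detect_changepoints(screened, penalty = penalty, min_seg = min_seg)
  adj <- adjust_recombination(screened, cps, alpha = alpha,
                              anchor_pos = mutation_pos)
  geno <- call_fetal_genotype(adj$series, alpha = alpha)
  ff <- estimate_fetal_fraction(adj$series, n_boot = n_boot)
  structure(list(call = geno$call,
                 mean_fraction = geno$mean_fraction,
                 p_value = geno$p_value,
                 recombination_detected = adj$recombination,
                 recomb_breakpoints = adj$breakpoint_pos,
                 fetal_fraction = ff$estimate,
                 fetal_fraction_ci = ff$ci,
                 qc = list(n_snps = length(raw$pos),
                           n_outliers = sum(!screened$retained),
                           n_used = sum(adj$series$retained),
                           mean_depth = mean(raw$a + raw$b)),
                 series = adj$series, series_raw = raw,
                 changepoints = cps, recombination = adj,
                 params = list(alpha = alpha, n_sigma = n_sigma,
                               min_seg = min_seg, penalty = penalty,
                               mutation_pos = mutation_pos)),
            class = "rhdo")
}

#' @describeIn rhdo one-line call summary.
#' @param x,object an \code{rhdo} object.
#' @param ... unused.
#' @export
print.rhdo <- function(x, ...) {
  cat(sprintf(paste0("<rhdo> call: %s (mean HapA fraction %.4f, p = %.3g)\n",
                     "  fetal fraction %.2f%%; recombination: %s; ",
                     "%d SNPs used (%d outliers masked)\n"),
              x$call, x$mean_fraction, x$p_value, 100 * x$fetal_fraction,
              if (x$recombination_detected)
                paste0("YES @ ", paste(format(round(x$recomb_breakpoints), big.mark = ","),
                                       collapse = ", "))
              else "none",
              x$qc$n_used, x$qc$n_outliers))
  invisible(x)
}

#' @describeIn rhdo structured summary (QC, changepoints, CI).
#' @export
summary.rhdo <- function(object, ...) {
  out <- list(call = object$call, mean_fraction = object$mean_fraction,
              p_value = object$p_value,
              recombination_detected = object$recombination_detected,
              recomb_breakpoints = object$recomb_breakpoints,
              fetal_fraction = object$fetal_fraction,
              fetal_fraction_ci = object$fetal_fraction_ci,
              n_changepoints_tested = length(object$changepoints$breakpoints),
              segment_means = object$changepoints$seg_means,
              qc = object$qc)
  class(out) <- "summary.rhdo"
  out
}

#' @export
print.summary.rhdo <- function(x, ...) {
  cat("Relative haplotype dosage analysis\n")
  cat(sprintf("  call:            %s\n", x$call))
  cat(sprintf("  HapA fraction:   %.4f (p = %.3g)\n", x$mean_fraction, x$p_value))
  cat(sprintf("  fetal fraction:  %.2f%%%s\n", 100 * x$fetal_fraction,
              if (!is.null(x$fetal_fraction_ci))
                sprintf(" (95%% CI %.2f-%.2f%%)", 100 * x$fetal_fraction_ci[1],
                        100 * x$fetal_fraction_ci[2]) else ""))
  cat(sprintf("  recombination:   %s\n",
              if (x$recombination_detected)
                paste(format(round(x$recomb_breakpoints), big.mark = ","), collapse = ", ")
              else "none detected"))
  cat(sprintf("  segments:        %s\n",
              paste(sprintf("%.4f", x$segment_means), collapse = " | ")))
  cat(sprintf("  QC:              %d SNPs, %d outliers masked, mean depth %.0fx\n",
              x$qc$n_snps, x$qc$n_outliers, x$qc$mean_depth))
  invisible(x)
}

#' @describeIn rhdo coefficients: pooled HapA fraction and fetal
#'   fraction.
#' @export
coef.rhdo <- function(object, ...) {
  c(hapA_fraction = object$mean_fraction,
    fetal_fraction = object$fetal_fraction)
}

#' @describeIn rhdo HapA read-fraction plot: per-SNP fractions, the
#'   pooled mean (red line), the 0.5 decision line, and arrows at
#'   confirmed recombination breakpoints.
#' @param adjusted plot the recombination-adjusted series (default) or
#'   the raw one.
#' @export
plot.rhdo <- function(x, adjusted = TRUE, ...) {
  s <- if (adjusted) x$series else x$series_raw
  keep <- s$retained
  plot(s$pos[keep] / 1e6, s$f[keep], type = "l", col = "grey40",
       xlab = "position (Mb)", ylab = "HapA read fraction",
       ylim = range(c(s$f[keep], 0.45, 0.55)), ...)
  abline(h = 0.5, lty = 2)
  abline(h = x$mean_fraction, col = "red")
  if (length(x$recomb_breakpoints)) {
    arrows(x$recomb_breakpoints / 1e6, par("usr")[4],
           x$recomb_breakpoints / 1e6,
           x$mean_fraction + 0.3 * (par("usr")[4] - x$mean_fraction),
           length = 0.1, col = "blue")
  }
  invisible(x)
}
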