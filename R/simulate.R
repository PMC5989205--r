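#' Simulate a carrier mother's diplotype
#'
#' Places \code{n_snps} heterozygous SNPs at uniform-random distinct
#' positions in the region, assigns each SNP's alleles to haplotype 1 or
#' 2 by a fair coin, and puts the pathogenic mutation on a seeded-coin
#' haplotype. All SNPs are heterozygous, so haplotype 2 is the exact
#' complement of haplotype 1.
#'
#' @param region a \code{\link{region_spec}}.
#' @param mutation a \code{\link{sv_mutation}}; must lie inside the
#'   region.
#' @param seed integer seed.
#' @return an object of class \code{maternal_diplotype}: a list with
#'   \code{region}, \code{mutation}, \code{mutation_hap} (1 or 2), and
#'   \code{snps}, a data.frame with columns \code{pos}, \code{ref},
#'   \code{alt} and \code{hap1} (0 = hap1 carries REF, 1 = hap1 carries
#'   ALT; hap2 always carries the other allele).
#' @export
simulate_diplotype <- function(region, mutation, seed = 1L) {
  stopifnot(inherits(region, "region_spec"), inherits(mutation, "sv_mutation"))
  if (mutation$start < region$start || mutation$end > region$end) {
    stop_hapdose("simulate_diplotype: mutation %s-%s outside region %s-%s",
                 mutation$start, mutation$end, region$start, region$end)
  }
  with_seed(seed, {
    pos <- sort(sample.int(region$end - region$start, region$n_snps)) +
      region$start - 1
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, region$n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    hap1 <- rbinom(region$n_snps, 1L, 0.5)
    mutation_hap <- sample(1:2, 1L)
    structure(list(region = region, mutation = mutation,
                   mutation_hap = mutation_hap,
                   snps = data.frame(pos = pos, ref = ref, alt = alt,
                                     hap1 = hap1, row.names = NULL)),
              class = "maternal_diplotype")
  })
}

# allele01 carried by haplotype `hap` (1 or 2) at every SNP
hap_alleles01 <- function(diplotype, hap) {
  if (hap == 1L) diplotype$snps$hap1 else 1L - diplotype$snps$hap1
}

#' True mutant-linked (HapA) allele vector of a simulated diplotype
#'
#' @param diplotype a \code{maternal_diplotype}.
#' @return integer vector of 0/1 (0 = REF): the allele carried by the
#'   mutation-bearing haplotype at every SNP.
#' @export
truth_hapA <- function(diplotype) {
  stopifnot(inherits(diplotype, "maternal_diplotype"))
  hap_alleles01(diplotype, diplotype$mutation_hap)
}

#' @export
print.maternal_diplotype <- function(x, ...) {
  cat(sprintf("<maternal_diplotype> %d het SNPs on %s; %s on haplotype %d\n",
              nrow(x$snps), x$region$chrom, x$mutation$kind, x$mutation_hap))
  invisible(x)
}

# Map positions from SV-excised coordinates back to reference coordinates
# (deletion carriers only): positions at or beyond the deletion start
# shift right by the deleted length.
.map_del <- function(pos, del_start, del_len) {
  pos + del_len * (pos >= del_start)
}

# SNP indices (into sorted positions `pos`) falling in [lo, hi)
.snps_in <- function(pos, lo, hi) {
  i0 <- findInterval(lo - 0.5, pos) + 1L
  i1 <- findInterval(hi - 0.5, pos)
  if (i1 < i0) integer() else c(i0, i1) # return range, not expansion
}

#' Simulate barcoded linked-read allele observations
#'
#' Molecules are drawn per haplotype with exponential lengths (mean
#' \code{molecule_mean_len}) and uniform placement, pooled into gems of
#' \code{molecules_per_gem} molecules each (a gem may mix haplotypes),
#' and short reads are sampled along each molecule to reach
#' \code{target_coverage} over the region. Each read covering a het SNP
#' emits one allele observation, flipped with probability
#' \code{seq_error_rate}.
#'
#' Mutation handling: molecules on a deletion-bearing haplotype are
#' placed on the excised genome and mapped back, so they span the
#' deletion junction and emit no observations inside the deleted
#' interval; on a duplication-bearing haplotype, SNPs inside the
#' duplicated interval are observed at doubled rate; for a point
#' mutation, reads covering the mutation site emit wild-type/mutant
#' observations recorded in \code{mutation_obs}.
#'
#' @param diplotype a \code{maternal_diplotype}.
#' @param params a \code{\link{sim_params}}.
#' @return an object of class \code{barcoded_read_set}: a list with
#'   \code{observations} (data.frame \code{barcode}, \code{snp},
#'   \code{allele}; allele is 0 = REF / 1 = ALT), \code{mutation_obs}
#'   (data.frame \code{barcode}, \code{allele}; 1 = mutant allele;
#'   non-empty for point mutations), \code{molecule_truth} (barcode,
#'   molecule, haplotype and reference-coordinate span, for oracles),
#'   \code{snp_pos} (positions of the SNP table) and \code{params}.
#' @export
simulate_linked_reads <- function(diplotype, params = sim_params()) {
  stopifnot(inherits(diplotype, "maternal_diplotype"),
            inherits(params, "sim_params"))
  reg <- diplotype$region
  mut <- diplotype$mutation
  pos <- diplotype$snps$pos
  L <- reg$end - reg$start
  mean_len <- params$molecule_mean_len
  # per-base read coverage within a molecule
  r_cov <- params$target_coverage / params$molecule_coverage

  empty <- function() {
    warning("simulate_linked_reads: zero coverage requested; empty read set")
    structure(list(observations = data.frame(barcode = integer(),
                                             snp = integer(),
                                             allele = integer()),
                   mutation_obs = data.frame(barcode = integer(),
                                             allele = integer()),
                   molecule_truth = data.frame(barcode = integer(),
                                               molecule = integer(),
                                               hap = integer(),
                                               start = numeric(),
                                               end = numeric()),
                   snp_pos = pos, params = params),
              class = "barcoded_read_set")
  }
  if (params$target_coverage == 0) return(empty())

  impl <- function() {
    mol <- list()
    for (h in 1:2) {
      carrier <- (h == diplotype$mutation_hap)
      del <- carrier && mut$kind == "deletion"
      del_len <- if (del) mut$end - mut$start else 0
      L_eff <- L - del_len
      n_mol <- rpois(1L, (params$molecule_coverage / 2) *
                       (L_eff + mean_len) / mean_len)
      if (n_mol == 0L) next
      len <- rexp(n_mol, 1 / mean_len)
      # uniform placement with overhang so interior coverage is flat;
      # coordinates are on the excised genome for deletion carriers
      s_eff <- reg$start - len + runif(n_mol) * (L_eff + len)
      e_eff <- s_eff + len
      if (del) {
        s_ref <- .map_del(s_eff, mut$start, del_len)
        e_ref <- .map_del(e_eff, mut$start, del_len)
      } else {
        s_ref <- s_eff; e_ref <- e_eff
      }
      mol[[h]] <- data.frame(hap = h, len = len, start = s_ref, end = e_ref)
    }
    mol <- do.call(rbind, mol)
    if (is.null(mol) || nrow(mol) == 0L) return(empty())
    n_mol <- nrow(mol)
    mol$molecule <- seq_len(n_mol)
    # gems: random pooling of molecules, molecules_per_gem per barcode
    perm <- sample.int(n_mol)
    mol$barcode <- (order(perm) - 1L) %/% params$molecules_per_gem + 1L
    mol$n_reads <- rpois(n_mol, mol$len * r_cov / params$read_len)
    p_read <- pmin(1, params$read_len / mol$len)

    # (molecule, snp) candidate rows; a deletion-spanning mutant molecule
    # contributes its two flank sub-intervals
    seg_lo <- mol$start
    seg_hi <- mol$end
    seg_mol <- seq_len(n_mol)
    if (mut$kind == "deletion") {
      mut_rows <- which(mol$hap == diplotype$mutation_hap)
      cross <- mut_rows[mol$start[mut_rows] < mut$start &
                          mol$end[mut_rows] > mut$end]
      if (length(cross)) {
        keep <- setdiff(seq_len(n_mol), cross)
        seg_lo <- c(mol$start[keep], mol$start[cross], rep(mut$end, length(cross)))
        seg_hi <- c(mol$end[keep], rep(mut$start, length(cross)), mol$end[cross])
        seg_mol <- c(keep, cross, cross)
      }
    }
    i0 <- findInterval(seg_lo - 0.5, pos) + 1L
    i1 <- findInterval(seg_hi - 0.5, pos)
    nsnp <- pmax(0L, i1 - i0 + 1L)
    has <- nsnp > 0L
    row_mol <- rep(seg_mol[has], nsnp[has])
    row_snp <- sequence(nsnp[has], from = i0[has])

    # observation counts per (molecule, SNP)
    p_obs <- p_read[row_mol]
    if (mut$kind == "duplication") {
      in_dup <- pos[row_snp] >= mut$start & pos[row_snp] < mut$end &
        mol$hap[row_mol] == diplotype$mutation_hap
      p_obs <- ifelse(in_dup, pmin(1, 2 * p_obs), p_obs)
    }
    nobs <- rbinom(length(row_mol), mol$n_reads[row_mol], p_obs)
    keep <- nobs > 0L
    obs_mol <- rep(row_mol[keep], nobs[keep])
    obs_snp <- rep(row_snp[keep], nobs[keep])

    hap1 <- diplotype$snps$hap1
    truth_allele <- ifelse(mol$hap[obs_mol] == 1L, hap1[obs_snp],
                           1L - hap1[obs_snp])
    if (params$seq_error_rate > 0) {
      flip <- rbinom(length(truth_allele), 1L, params$seq_error_rate)
      truth_allele <- as.integer(xor(truth_allele, flip))
    }
    observations <- data.frame(barcode = mol$barcode[obs_mol],
                               snp = obs_snp,
                               allele = as.integer(truth_allele))

    # point mutation: reads over the mutation site (not a het SNP)
    mutation_obs <- data.frame(barcode = integer(), allele = integer())
    if (mut$kind == "point") {
      covers <- which(mol$start <= mut$start & mol$end > mut$start)
      if (length(covers)) {
        nm <- rbinom(length(covers), mol$n_reads[covers], p_read[covers])
        mol_id <- rep(covers, nm)
        if (length(mol_id)) {
          al <- as.integer(mol$hap[mol_id] == diplotype$mutation_hap)
          if (params$seq_error_rate > 0) {
            flip <- rbinom(length(al), 1L, params$seq_error_rate)
            al <- as.integer(xor(al, flip))
          }
          mutation_obs <- data.frame(barcode = mol$barcode[mol_id], allele = al)
        }
      }
    }

    structure(list(observations = observations,
                   mutation_obs = mutation_obs,
                   molecule_truth = data.frame(barcode = mol$barcode,
                                               molecule = mol$molecule,
                                               hap = mol$hap,
                                               start = mol$start,
                                               end = mol$end),
                   snp_pos = pos, params = params),
              class = "barcoded_read_set")
  }
  with_seed(params$seed, impl())
}

#' @export
print.barcoded_read_set <- function(x, ...) {
  cat(sprintf(paste0("<barcoded_read_set> %s allele observations, ",
                     "%d barcodes, %d molecules, %d SNPs\n"),
              format(nrow(x$observations), big.mark = ","),
              length(unique(x$molecule_truth$barcode)),
              nrow(x$molecule_truth), length(x$snp_pos)))
  invisible(x)
}

# Copy number of each haplotype at each SNP given the mutation
.copy_number <- function(diplotype) {
  pos <- diplotype$snps$pos
  n <- length(pos)
  c1 <- rep(1, n); c2 <- rep(1, n)
  mut <- diplotype$mutation
  if (mut$kind %in% c("deletion", "duplication")) {
    inside <- pos >= mut$start & pos < mut$end
    mult <- if (mut$kind == "deletion") 0 else 2
    if (diplotype$mutation_hap == 1L) c1[inside] <- mult else c2[inside] <- mult
  }
  list(c1 = c1, c2 = c2)
}

# Per-SNP fetal haplotype index (1/2) from transmitted hap + breakpoints
fetal_hap_vector <- function(n_snps, transmitted_hap, breakpoints) {
  if (length(breakpoints) &&
      (min(breakpoints) < 1L || max(breakpoints) > n_snps - 1L)) {
    stop_hapdose("recomb breakpoint index out of range 1..%d", n_snps - 1L)
  }
  flips <- findInterval(seq_len(n_snps) - 1L, breakpoints)
  ifelse(flips %% 2L == 0L, transmitted_hap, 3L - transmitted_hap)
}

#' Simulate plasma cfDNA allelic depths
#'
#' For each SNP the expected haplotype-1 allele fraction follows copy
#' accounting of X genome equivalents: the mother contributes
#' \code{(1 - phi)/2} per haplotype copy and the male fetus \code{phi}
#' on his single X, with \code{phi = f / (2 - f)}. At copy-neutral SNPs
#' this reduces to \code{p = (1 - phi)/2 + phi * [fetal allele ==
#' hap1 allele]}; inside a deletion or duplication the maternal (and
#' fetal) site copy numbers enter the mixture, so such SNPs show the
#' aberrant fractions that the downstream outlier screen removes.
#' Depths are drawn as \code{a ~ Binomial(depth_per_snp, p)},
#' \code{b = depth_per_snp - a}.
#'
#' @param diplotype a \code{maternal_diplotype}.
#' @param spec a \code{\link{plasma_spec}}.
#' @param seed integer seed.
#' @return an object of class \code{plasma_counts}: a data.frame with
#'   columns \code{pos}, \code{ref_count}, \code{alt_count}, carrying a
#'   \code{truth} attribute (fetal haplotype vector, expected fractions,
#'   \code{phi}, fetal fraction, breakpoints, transmitted haplotype and
#'   the hap1-allele counts).
#' @export
simulate_plasma <- function(diplotype, spec, seed = 1L) {
  stopifnot(inherits(diplotype, "maternal_diplotype"),
            inherits(spec, "plasma_spec"))
  n <- nrow(diplotype$snps)
  fhap <- fetal_hap_vector(n, spec$transmitted_hap, spec$recomb_breakpoints)
  f <- spec$fetal_fraction
  phi <- f / (2 - f)
  cn <- .copy_number(diplotype)
  cf <- ifelse(fhap == 1L, cn$c1, cn$c2)
  num <- (1 - phi) / 2 * cn$c1 + phi * cf * (fhap == 1L)
  den <- (1 - phi) / 2 * (cn$c1 + cn$c2) + phi * cf
  p <- num / den
  with_seed(seed, {
    a <- rbinom(n, spec$depth_per_snp, p) # hap1-allele depth
    b <- spec$depth_per_snp - a
    hap1 <- diplotype$snps$hap1
    counts <- data.frame(pos = diplotype$snps$pos,
                         ref_count = ifelse(hap1 == 0L, a, b),
                         alt_count = ifelse(hap1 == 0L, b, a))
    structure(counts,
              truth = list(fetal_hap = fhap, p = p, phi = phi,
                           fetal_fraction = f,
                           transmitted_hap = spec$transmitted_hap,
                           breakpoints = spec$recomb_breakpoints,
                           hap1_count = a),
              class = c("plasma_counts", "data.frame"))
  })
}

#' Simulate a complete family dataset
#'
#' One carrier mother (diplotype + linked reads) plus zero or more
#' plasma draws, with a truth record sufficient for scoring every
#' downstream call. Sub-seeds for the diplotype, the read simulation and
#' each plasma draw are derived from \code{seed} via
#' \code{\link{stage_seed}}, so the dataset is reproducible end to end.
#'
#' @param config a list (see \code{\link{family_config}}).
#' @param seed integer seed; overrides \code{config$seed} if given.
#' @return an object of class \code{family_dataset}: list with
#'   \code{name}, \code{diplotype}, \code{reads}, \code{plasma} (list of
#'   \code{plasma_counts}) and \code{truth}.
#' @export
simulate_family <- function(config, seed = NULL) {
  config <- validate_family_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dip <- simulate_diplotype(config$region, config$mutation,
                            seed = stage_seed(seed, paste0("diplotype/", config$name)))
  prm <- config$params
  prm$seed <- stage_seed(seed, paste0("reads/", config$name))
  reads <- simulate_linked_reads(dip, prm)
  plasma <- list()
  truth_draws <- list()
  n <- nrow(dip$snps)
  for (k in seq_along(config$draws)) {
    d <- config$draws[[k]]
    # "mutant"/"wildtype" resolve against the seeded mutation haplotype
    th <- switch(d$transmitted,
                 mutant = dip$mutation_hap,
                 wildtype = 3L - dip$mutation_hap)
    ps <- plasma_spec(fetal_fraction = d$fetal_fraction, transmitted_hap = th,
                      recomb_breakpoints = d$recomb_breakpoints %||% integer(),
                      depth_per_snp = d$depth_per_snp %||% 200L)
    plasma[[k]] <- simulate_plasma(dip, ps,
                                   seed = stage_seed(seed, sprintf("plasma/%s/%d", config$name, k)))
    # clinically relevant truth: fetal haplotype at the mutation locus
    fhap <- attr(plasma[[k]], "truth")$fetal_hap
    mut_idx <- max(1L, findInterval(config$mutation$start, dip$snps$pos))
    truth_draws[[k]] <- list(fetal_fraction = d$fetal_fraction,
                             transmitted_hap = th,
                             breakpoints = ps$recomb_breakpoints,
                             recombination = length(ps$recomb_breakpoints) > 0L,
                             fetal_hap_at_mutation = fhap[mut_idx],
                             call = if (fhap[mut_idx] == dip$mutation_hap)
                               "mutant_inherited" else "wildtype_inherited")
  }
  structure(list(name = config$name, config = config, seed = seed,
                 diplotype = dip, reads = reads, plasma = plasma,
                 truth = list(mutation_hap = dip$mutation_hap,
                              hapA = truth_hapA(dip),
                              draws = truth_draws)),
            class = "family_dataset")
}

#' Build a family simulation config
#'
#' @param name family label.
#' @param mutation a \code{\link{sv_mutation}}.
#' @param draws list of plasma draws; each a list with
#'   \code{fetal_fraction}, \code{transmitted} (\code{"mutant"} or
#'   \code{"wildtype"}), and optionally \code{recomb_breakpoints} and
#'   \code{depth_per_snp}.
#' @param region a \code{\link{region_spec}}.
#' @param params a \code{\link{sim_params}}.
#' @param seed default seed for \code{\link{simulate_family}}.
#' @return a validated config list.
#' @export
family_config <- function(name, mutation, draws = list(),
                          region = region_spec(), params = sim_params(),
                          seed = 1L) {
  validate_family_config(list(name = name, mutation = mutation, draws = draws,
                              region = region, params = params, seed = seed))
}

validate_family_config <- function(config) {
  for (f in c("name", "mutation", "region")) {
    if (is.null(config[[f]])) stop_hapdose("family config: missing field '%s'", f)
  }
  if (!inherits(config$region, "region_spec")) {
    stop_hapdose("family config '%s': field 'region' is not a region_spec", config$name)
  }
  if (!inherits(config$mutation, "sv_mutation")) {
    stop_hapdose("family config '%s': field 'mutation' is not an sv_mutation", config$name)
  }
  config$params <- config$params %||% sim_params()
  if (!inherits(config$params, "sim_params")) {
    stop_hapdose("family config '%s': field 'params' is not sim_params", config$name)
  }
  config$draws <- config$draws %||% list()
  for (k in seq_along(config$draws)) {
    d <- config$draws[[k]]
    if (is.null(d$fetal_fraction)) {
      stop_hapdose("family config '%s': draw %d missing field 'fetal_fraction'",
                   config$name, k)
    }
    if (is.null(d$transmitted) || !d$transmitted %in% c("mutant", "wildtype")) {
      stop_hapdose("family config '%s': draw %d field 'transmitted' must be 'mutant' or 'wildtype'",
                   config$name, k)
    }
  }
  config
}

#' The five-family study cohort configuration
#'
#' Encodes the study cohort used throughout the package's acceptance
#' simulations: five carrier mothers with different mutation classes and
#' nine plasma draws at the printed fractional fetal DNA concentrations
#' (4.10-9.25\%), all male fetuses, 850 informative het SNPs over a
#' 2.2 Mb chrX target, 200x plasma depth. Family 5 carries the single
#' fetal recombination event (one crossover, placed mid-region, with the
#' mutant haplotype transmitted at the mutation locus).
#'
#' @param n_snps informative het SNPs per mother.
#' @param depth_per_snp plasma depth per SNP.
#' @param params a \code{\link{sim_params}} shared by all mothers.
#' @return list of five family configs for \code{\link{simulate_family}}.
#' @export
dmd_cohort <- function(n_snps = 850, depth_per_snp = 200,
                       params = sim_params()) {
  reg <- function() region_spec("chrX", 31100000, 33300000, n_snps)
  draw <- function(f, tr, bp = integer()) {
    list(fetal_fraction = f, transmitted = tr, recomb_breakpoints = bp,
         depth_per_snp = depth_per_snp)
  }
  list(
    family_config("DMD-01",
                  sv_mutation("deletion", 31880000, 32020000, "exons 49-52 del"),
                  list(draw(0.0566, "wildtype"), draw(0.0774, "wildtype")),
                  region = reg(), params = params),
    family_config("DMD-02",
                  sv_mutation("duplication", 33020000, 33080000, "exon 2 dup"),
                  list(draw(0.0925, "mutant"), draw(0.0685, "mutant")),
                  region = reg(), params = params),
    family_config("DMD-03",
                  sv_mutation("deletion", 32830000, 32950000, "exons 3-7 del"),
                  list(draw(0.0634, "mutant"), draw(0.0880, "mutant")),
                  region = reg(), params = params),
    family_config("DMD-04",
                  sv_mutation("point", 32841237, description = "c.649+2T>C"),
                  list(draw(0.0624, "mutant")),
                  region = reg(), params = params),
    family_config("DMD-05",
                  sv_mutation("deletion", 31660000, 31900000, "exons 52-62 del"),
                  list(draw(0.0410, "mutant", bp = as.integer(round(n_snps / 2))),
                       draw(0.0507, "mutant", bp = as.integer(round(n_snps / 2)))),
                  region = reg(), params = params)
  )
}
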