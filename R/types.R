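#' Describe the target region
#'
#' A targeted locus on one chromosome with a stated number of informative
#' (maternally heterozygous) SNPs. Coordinates are 0-based half-open
#' throughout the package; VCF output converts to 1-based.
#'
#' @param chrom chromosome label, e.g. \code{"chrX"}.
#' @param start,end region bounds in bp, 0-based half-open.
#' @param n_snps number of informative het SNPs to place (>= 2). The
#'   motivating regime is 700-1000 SNPs over ~2.2 Mb.
#' @return an object of class \code{region_spec}.
#' @export
region_spec <- function(chrom = "chrX", start = 31100000, end = 33300000,
                        n_snps = 850) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  n_snps <- as.integer(n_snps)
  if (!(end > start)) stop_hapdose("region_spec: end (%s) must exceed start (%s)", end, start)
  if (n_snps < 2L) stop_hapdose("region_spec: n_snps must be >= 2, got %d", n_snps)
  if (n_snps > end - start) {
    stop_hapdose("region_spec: n_snps (%d) exceeds region size (%s bp)", n_snps, end - start)
  }
  structure(list(chrom = chrom, start = start, end = end, n_snps = n_snps),
            class = "region_spec")
}

#' Describe the pathogenic mutation
#'
#' @param kind one of \code{"deletion"}, \code{"duplication"},
#'   \code{"point"}.
#' @param start,end mutation bounds in bp, 0-based half-open; for a point
#'   mutation \code{end == start + 1}.
#' @param description free text (e.g. an exon range or HGVS string).
#' @return an object of class \code{sv_mutation}.
#' @export
sv_mutation <- function(kind, start, end = start + 1, description = "") {
  kind <- match.arg(kind, c("deletion", "duplication", "point"))
  start <- as.numeric(start); end <- as.numeric(end)
  if (end < start) stop_hapdose("sv_mutation: end < start")
  if (kind == "point" && end != start + 1) {
    stop_hapdose("sv_mutation: a point mutation must have end == start + 1")
  }
  if (kind != "point" && end == start) {
    stop_hapdose("sv_mutation: zero-length %s", kind)
  }
  structure(list(kind = kind, start = start, end = end,
                 description = description), class = "sv_mutation")
}

#' Linked-read simulation parameters
#'
#' Defaults state the emulated sequencing regime: high-molecular-weight
#' input averaging 52.7 kb, deep targeted read coverage of 676x, and a
#' physical (molecule) coverage of 300x, i.e. about 150
#' genome-equivalents per haplotype — a standard ~1 ng Chromium load.
#'
#' @param molecule_mean_len mean HMW molecule length in bp (exponential
#'   length model).
#' @param molecules_per_gem number of molecules pooled per barcode; gems
#'   may mix molecules from both haplotypes.
#' @param molecule_coverage physical molecule coverage (both haplotypes
#'   combined) over the region.
#' @param target_coverage read (base) coverage to emit over the region.
#' @param read_len read length in bp.
#' @param seq_error_rate per-observation allele flip probability in
#'   \code{[0, 0.5)}.
#' @param seed integer seed for the read simulation.
#' @return an object of class \code{sim_params}.
#' @export
sim_params <- function(molecule_mean_len = 52700, molecules_per_gem = 10,
                       molecule_coverage = 300, target_coverage = 676,
                       read_len = 150, seq_error_rate = 0.001, seed = 1L) {
  p <- list(molecule_mean_len = as.numeric(molecule_mean_len),
            molecules_per_gem = as.integer(molecules_per_gem),
            molecule_coverage = as.numeric(molecule_coverage),
            target_coverage = as.numeric(target_coverage),
            read_len = as.numeric(read_len),
            seq_error_rate = as.numeric(seq_error_rate),
            seed = as.integer(seed))
  num <- c("molecule_mean_len", "molecules_per_gem", "molecule_coverage",
           "read_len")
  for (f in num) if (p[[f]] <= 0) stop_hapdose("sim_params: %s must be positive", f)
  if (p$target_coverage < 0) stop_hapdose("sim_params: target_coverage must be >= 0")
  if (p$seq_error_rate < 0 || p$seq_error_rate >= 0.5) {
    stop_hapdose("sim_params: seq_error_rate must lie in [0, 0.5)")
  }
  structure(p, class = "sim_params")
}

#' Plasma draw specification
#'
#' The fetal fraction \code{f} is defined on autosomal genome
#' equivalents. With a male fetus the fetal share of chrX reads is
#' \code{phi = f / (2 - f)}: the mother contributes two X copies per
#' genome equivalent, the fetus one.
#'
#' @param fetal_fraction proportion of fetal cfDNA, in \code{[0, 1)}.
#' @param transmitted_hap maternal haplotype (1 or 2) transmitted at the
#'   region start; flips across each recombination breakpoint.
#' @param recomb_breakpoints strictly increasing SNP-interval indices:
#'   value \code{k} places a fetal crossover between SNP \code{k} and
#'   \code{k + 1}.
#' @param depth_per_snp plasma sequencing depth at each SNP.
#' @param fetus_male must be \code{TRUE}; only male fetuses are modelled.
#' @return an object of class \code{plasma_spec}.
#' @export
plasma_spec <- function(fetal_fraction, transmitted_hap = 1L,
                        recomb_breakpoints = integer(), depth_per_snp = 200,
                        fetus_male = TRUE) {
  f <- as.numeric(fetal_fraction)
  if (f < 0 || f >= 1) stop_hapdose("plasma_spec: fetal_fraction must lie in [0, 1)")
  transmitted_hap <- as.integer(transmitted_hap)
  if (!transmitted_hap %in% 1:2) stop_hapdose("plasma_spec: transmitted_hap must be 1 or 2")
  bp <- as.integer(recomb_breakpoints)
  if (length(bp) && any(diff(bp) <= 0)) {
    stop_hapdose("plasma_spec: recomb_breakpoints must be strictly increasing")
  }
  if (!isTRUE(fetus_male)) stop_hapdose("plasma_spec: only male fetuses are modelled")
  structure(list(fetal_fraction = f, transmitted_hap = transmitted_hap,
                 recomb_breakpoints = bp,
                 depth_per_snp = as.integer(depth_per_snp),
                 fetus_male = TRUE),
            class = "plasma_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %s:%s-%s (%.2f Mb), %d het SNPs\n",
              x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","), (x$end - x$start) / 1e6, x$n_snps))
  invisible(x)
}

#' @export
print.sv_mutation <- function(x, ...) {
  cat(sprintf("<sv_mutation> %s %s-%s%s\n", x$kind,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              if (nzchar(x$description)) paste0(" (", x$description, ")") else ""))
  invisible(x)
}
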