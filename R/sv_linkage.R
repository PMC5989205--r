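# Evidence scan shared by anchoring and SV linkage: which barcodes
# support the mutant (SV-bearing) haplotype and which the wild type.
#
# Deletion: barcodes with observations inside the deleted interval carry
# the wild-type haplotype there; barcodes whose observations bracket the
# interval (>= 1 observation within flank_bp on each side) without any
# interior observation behave like molecules spanning the deletion
# junction and support the mutant haplotype.
#
# Duplication: the interval's het SNPs show a 2:1 copy imbalance, so the
# duplicated haplotype's allele runs at ~2/3 pooled frequency; gems
# containing reads with the overrepresented allele at such divergent
# SNPs support the mutant haplotype.
sv_supporting_barcodes <- function(reads, mutation, flank_bp = NULL,
                                   af_low = 0.4, af_high = 0.6) {
  pos <- reads$snp_pos
  obs <- reads$observations
  opos <- pos[obs$snp]
  if (mutation$kind == "deletion") {
    flank_bp <- flank_bp %||% (1.5 * reads$params$molecule_mean_len)
    interior <- opos >= mutation$start & opos < mutation$end
    wt <- unique(obs$barcode[interior])
    f5 <- unique(obs$barcode[opos >= mutation$start - flank_bp &
                               opos < mutation$start])
    f3 <- unique(obs$barcode[opos >= mutation$end &
                               opos < mutation$end + flank_bp])
    mutant <- setdiff(intersect(f5, f3), wt)
    list(mutant = mutant, wildtype = wt)
  } else if (mutation$kind == "duplication") {
    div <- divergent_dup_snps(reads, mutation, af_low, af_high)
    if (!nrow(div)) return(list(mutant = integer(), wildtype = integer()))
    key <- paste(obs$snp, obs$allele)
    over <- unique(obs$barcode[key %in% paste(div$snp, div$over_allele)])
    under <- unique(obs$barcode[key %in% paste(div$snp, 1L - div$over_allele)])
    both <- intersect(over, under)
    list(mutant = setdiff(over, both), wildtype = setdiff(under, both))
  } else {
    stop_hapdose("sv_supporting_barcodes: mutation kind '%s' is not an SV",
                 mutation$kind)
  }
}

# Pooled allele fractions at SNPs inside a duplication; returns the
# divergent SNPs (alt fraction outside [af_low, af_high]) with their
# overrepresented allele.
divergent_dup_snps <- function(reads, mutation, af_low, af_high) {
  pos <- reads$snp_pos
  idx <- which(pos >= mutation$start & pos < mutation$end)
  obs <- reads$observations
  inside <- obs[obs$snp %in% idx, , drop = FALSE]
  if (!nrow(inside)) {
    return(data.frame(snp = integer(), af = numeric(), over_allele = integer()))
  }
  alt_n <- tapply(inside$allele, inside$snp, sum)
  tot_n <- tapply(inside$allele, inside$snp, length)
  af <- as.numeric(alt_n) / as.numeric(tot_n)
  snp <- as.integer(names(tot_n))
  divergent <- af < af_low | af > af_high
  data.frame(snp = snp[divergent], af = af[divergent],
             over_allele = as.integer(af[divergent] > 0.5))
}

#' Link a large deletion to a phased haplotype
#'
#' Classifies barcodes as wild-type-supporting (observations inside the
#' deleted interval) or mutant-supporting (observations bracketing the
#' interval within \code{flank_bp} on both sides, none inside), then
#' checks (a) that the mutant barcodes' flank observations are mutually
#' phase-consistent across the gap — the allele-level equivalent of
#' re-aligning them to a deletion reference — and (b) that the het SNPs
#' immediately 5' and 3' of the deletion phase to one haplotype. The
#' majority haplotype among cross-gap-consistent mutant barcodes is the
#' deletion-bearing strand.
#'
#' @param reads a \code{barcoded_read_set}.
#' @param deletion an \code{\link{sv_mutation}} of kind
#'   \code{"deletion"}; its interval must contain at least one het SNP
#'   and have at least one het SNP within \code{flank_bp} on each side.
#' @param pair a \code{haplotype_pair}.
#' @param flank_bp flank window; default 1.5 x the simulated (or
#'   assumed) mean molecule length, tying "spanning" to molecule scale.
#' @return an \code{sv_linkage} object: list with \code{kind},
#'   \code{strand} ("hapA"/"hapB"), \code{is_hapA},
#'   \code{mutant_barcodes}, \code{wildtype_barcodes},
#'   \code{flank_check}, \code{consistent_fraction}, \code{confidence}
#'   and counts.
#' @export
link_deletion <- function(reads, deletion, pair, flank_bp = NULL) {
  stopifnot(inherits(pair, "haplotype_pair"))
  if (deletion$kind != "deletion") stop_hapdose("link_deletion: mutation is not a deletion")
  flank_bp <- flank_bp %||% (1.5 * reads$params$molecule_mean_len)
  pos <- reads$snp_pos
  interior_idx <- which(pos >= deletion$start & pos < deletion$end)
  if (!length(interior_idx)) {
    stop_hapdose("link_deletion: deletion interval contains no het SNP")
  }
  left_idx <- which(pos >= deletion$start - flank_bp & pos < deletion$start)
  right_idx <- which(pos >= deletion$end & pos < deletion$end + flank_bp)
  if (!length(left_idx) || !length(right_idx)) {
    stop_hapdose("link_deletion: no het SNP within %g bp on each side", flank_bp)
  }
  sets <- sv_supporting_barcodes(reads, deletion, flank_bp = flank_bp)
  if (!length(sets$mutant)) {
    stop_hapdose("deletion not linkable: no barcodes span the deleted interval")
  }
  calls <- barcode_calls(build_barcode_matrix(reads))
  calls <- calls[calls$barcode %in% sets$mutant & !is.na(pair$hapA[calls$snp])]
  # signed orientation per barcode and flank: + = resembles HapA
  side <- ifelse(calls$snp %in% left_idx, "L",
                 ifelse(calls$snp %in% right_idx, "R", NA))
  calls <- calls[!is.na(side)]
  side <- side[!is.na(side)]
  v <- ifelse(calls$call == pair$hapA[calls$snp], 1L, -1L)
  vL <- tapply(v[side == "L"], calls$barcode[side == "L"], sum)
  vR <- tapply(v[side == "R"], calls$barcode[side == "R"], sum)
  common <- intersect(names(vL), names(vR))
  if (!length(common)) {
    stop_hapdose("deletion not linkable: spanning barcodes have no phased flank calls")
  }
  sL <- sign(vL[common]); sR <- sign(vR[common])
  consistent <- sL != 0 & sR != 0 & sL == sR
  consistent_fraction <- mean(consistent)
  voters <- sL[consistent]
  if (!length(voters)) {
    stop_hapdose("deletion not linkable: no cross-gap-consistent spanning barcode")
  }
  score <- sum(voters)
  strand <- if (score > 0) "hapA" else if (score < 0) "hapB" else NA_character_
  if (is.na(strand)) stop_hapdose("deletion not linkable: spanning barcodes split evenly")
  confidence <- max(sum(voters > 0), sum(voters < 0)) / length(voters)

  # flank check: nearest phased het SNPs either side of the gap must sit
  # on the same haplotype as seen by the mutant barcodes
  flank_check <- local({
    l <- max(left_idx[!is.na(pair$hapA[left_idx])] %||% integer(), -Inf)
    r <- min(right_idx[!is.na(pair$hapA[right_idx])] %||% integer(), Inf)
    if (!is.finite(l) || !is.finite(r)) return(FALSE)
    maj <- function(i) {
      cc <- calls$call[calls$snp == i]
      if (!length(cc)) return(NA_integer_)
      s <- mean(cc)
      if (s == 0.5) NA_integer_ else as.integer(s > 0.5)
    }
    al <- maj(l); ar <- maj(r)
    if (is.na(al) || is.na(ar)) return(FALSE)
    (al == pair$hapA[l]) == (ar == pair$hapA[r])
  })
  structure(list(kind = "deletion", strand = strand,
                 is_hapA = strand == "hapA",
                 mutant_barcodes = sets$mutant,
                 wildtype_barcodes = sets$wildtype,
                 flank_check = flank_check,
                 consistent_fraction = consistent_fraction,
                 confidence = confidence,
                 n_mutant = length(sets$mutant),
                 n_wildtype = length(sets$wildtype)),
            class = "sv_linkage")
}

#' Link a large duplication to a phased haplotype
#'
#' SNPs inside the duplicated interval whose pooled alt-allele fraction
#' falls outside \code{[af_low, af_high]} are divergent: the
#' overrepresented allele (expected frequency ~2/3 from the 2:1 copy
#' imbalance) identifies the duplicated haplotype. Each divergent SNP
#' votes for the strand carrying its overrepresented allele; the
#' majority sets the linkage, and a split vote below 75\% is flagged
#' low-confidence.
#'
#' @param reads a \code{barcoded_read_set}.
#' @param duplication an \code{\link{sv_mutation}} of kind
#'   \code{"duplication"}; must contain at least one het SNP.
#' @param pair a \code{haplotype_pair}.
#' @param af_low,af_high the non-divergent allele-fraction band. At
#'   ~600x pooled depth the default [0.4, 0.6] band gives <1\% per-SNP
#'   false positives on balanced SNPs while 2/3 vs 1/3 signals pass.
#' @return an \code{sv_linkage} object (see \code{\link{link_deletion}})
#'   with additionally \code{divergent_snps} and
#'   \code{low_confidence}.
#' @export
link_duplication <- function(reads, duplication, pair, af_low = 0.4,
                             af_high = 0.6) {
  stopifnot(inherits(pair, "haplotype_pair"))
  if (duplication$kind != "duplication") {
    stop_hapdose("link_duplication: mutation is not a duplication")
  }
  pos <- reads$snp_pos
  if (!any(pos >= duplication$start & pos < duplication$end)) {
    stop_hapdose("link_duplication: duplication interval contains no het SNP")
  }
  div <- divergent_dup_snps(reads, duplication, af_low, af_high)
  if (!nrow(div)) {
    stop_hapdose("duplication not linkable: no SNP with divergent allele fraction in [%s, %s] complement",
                 af_low, af_high)
  }
  phased <- !is.na(pair$hapA[div$snp])
  votes <- ifelse(pair$hapA[div$snp[phased]] == div$over_allele[phased],
                  "hapA", "hapB")
  if (!length(votes)) {
    stop_hapdose("duplication not linkable: divergent SNPs are all unphased")
  }
  tab <- c(hapA = sum(votes == "hapA"), hapB = sum(votes == "hapB"))
  strand <- names(tab)[which.max(tab)]
  confidence <- max(tab) / sum(tab)
  sets <- sv_supporting_barcodes(reads, duplication, af_low = af_low,
                                 af_high = af_high)
  structure(list(kind = "duplication", strand = strand,
                 is_hapA = strand == "hapA",
                 mutant_barcodes = sets$mutant,
                 wildtype_barcodes = sets$wildtype,
                 flank_check = NA, # defined only for deletions
                 divergent_snps = div,
                 confidence = confidence,
                 low_confidence = confidence < 0.75,
                 n_mutant = length(sets$mutant),
                 n_wildtype = length(sets$wildtype)),
            class = "sv_linkage")
}

#' Link any SV class to a phased haplotype
#'
#' Dispatches on the mutation kind.
#'
#' @inheritParams link_deletion
#' @param mutation an \code{\link{sv_mutation}} of kind
#'   \code{"deletion"} or \code{"duplication"}.
#' @param ... forwarded to the class-specific linker.
#' @return an \code{sv_linkage} object.
#' @export
link_sv <- function(reads, mutation, pair, ...) {
  switch(mutation$kind,
         deletion = link_deletion(reads, mutation, pair, ...),
         duplication = link_duplication(reads, mutation, pair, ...),
         stop_hapdose("link_sv: kind '%s' is not a structural variant",
                      mutation$kind))
}

#' @export
print.sv_linkage <- function(x, ...) {
  cat(sprintf(paste0("<sv_linkage> %s linked to %s (confidence %.2f; ",
                     "%d mutant / %d wild-type barcodes%s)\n"),
              x$kind, x$strand, x$confidence, x$n_mutant, x$n_wildtype,
              if (x$kind == "deletion")
                sprintf("; flank check %s", ifelse(isTRUE(x$flank_check), "pass", "FAIL"))
              else ""))
  invisible(x)
}
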