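# Format adapters. Internal coordinates are 0-based half-open; VCF is
# 1-based inclusive and BED 0-based half-open, with the conversions kept
# in this file only.

bed0_to_vcf1 <- function(start, end) list(start = start + 1, end = end)
vcf1_to_bed0 <- function(start, end) list(start = start - 1, end = end)

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stop_hapdose("file not found: %s", path)
  readLines(path)
}

.split_tsv <- function(lines, n_fields, path, skip = 0L) {
  out <- strsplit(lines, "\t", fixed = TRUE)
  for (k in seq_along(out)) {
    if (length(out[[k]]) < n_fields) {
      stop_hapdose("%s: line %d: expected %d tab-separated fields, got %d",
                   path, k + skip, n_fields, length(out[[k]]))
    }
  }
  out
}

#' Write maternal het SNPs with phasing as VCF 4.2
#'
#' Genotypes are written phased (\code{GT = hapA|hapB}, i.e. the first
#' allele of every phased genotype is the mutant-linked HapA allele, as
#' declared in the header) with \code{PS} set to the position of the
#' block's first SNP; unphased SNPs are written \code{0/1}.
#'
#' @param pair a \code{haplotype_pair} (or a \code{maternal_diplotype},
#'   in which case the truth phase hap1|hap2 is written and HapA is the
#'   mutation haplotype).
#' @param snps data.frame with \code{pos}, \code{ref}, \code{alt}
#'   (ignored when \code{pair} is a diplotype).
#' @param path output path.
#' @param chrom chromosome label.
#' @param sample sample name.
#' @return \code{path}, invisibly.
#' @export
write_phased_vcf <- function(pair, snps = NULL, path, chrom = "chrX",
                             sample = "MOTHER") {
  if (inherits(pair, "maternal_diplotype")) {
    snps <- pair$snps
    chrom <- pair$region$chrom
    hapA <- truth_hapA(pair)
    ps <- rep(snps$pos[1] + 1, nrow(snps))
  } else {
    stopifnot(inherits(pair, "haplotype_pair"), !is.null(snps))
    hapA <- pair$hapA
    ps <- rep(NA_real_, length(hapA))
    for (b in pair$blocks$blocks) ps[b$snps] <- min(snps$pos[b$snps]) + 1
    ps[is.na(hapA)] <- NA
  }
  gt <- ifelse(is.na(hapA), "0/1", paste0(hapA, "|", 1L - hapA))
  fmt <- ifelse(is.na(hapA), gt, paste0(gt, ":", format(ps, scientific = FALSE,
                                                        trim = TRUE)))
  fmt_key <- ifelse(is.na(hapA), "GT", "GT:PS")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hapdose",
    paste0("##contig=<ID=", chrom, ">"),
    "##hapdose_convention=first allele of phased GT is the mutant-linked haplotype (HapA)",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set (position of first SNP in phase block)">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  body <- paste(chrom, format(snps$pos + 1, scientific = FALSE, trim = TRUE),
                ".", snps$ref, snps$alt, ".", "PASS", ".", fmt_key, fmt,
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF written by this package
#'
#' Minimal reader for the package's own VCF dialect: fixed columns, one
#' sample, GT (optionally phased) and PS.
#'
#' @param path VCF path.
#' @return list with \code{pos} (0-based), \code{ref}, \code{alt},
#'   \code{hapA} (first GT allele where phased, NA otherwise),
#'   \code{phased} and \code{ps}.
#' @export
read_phased_vcf <- function(path) {
  lines <- .read_lines_checked(path)
  hdr <- startsWith(lines, "#")
  body <- lines[!hdr]
  if (!length(body)) stop_hapdose("%s: no variant records", path)
  fields <- .split_tsv(body, 10L, path, skip = sum(hdr))
  pos1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos1)) {
    stop_hapdose("%s: line %d: malformed POS", path,
                 sum(hdr) + which(is.na(pos1))[1L])
  }
  sample_f <- vapply(fields, `[[`, "", 10L)
  gt <- vapply(strsplit(sample_f, ":", fixed = TRUE), `[[`, "", 1L)
  phased <- grepl("|", gt, fixed = TRUE)
  first <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
  ps <- rep(NA_real_, length(gt))
  has_ps <- phased & grepl(":", sample_f, fixed = TRUE)
  ps[has_ps] <- as.numeric(vapply(strsplit(sample_f[has_ps], ":", fixed = TRUE),
                                  `[[`, "", 2L))
  list(pos = pos1 - 1,
       ref = vapply(fields, `[[`, "", 4L),
       alt = vapply(fields, `[[`, "", 5L),
       hapA = ifelse(phased, first, NA_integer_),
       phased = phased, ps = ps)
}

#' Write/read barcoded allele observations as TSV
#'
#' Dialect: header line, then
#' \code{barcode<TAB>snp_index<TAB>pos<TAB>allele} with allele
#' \code{ref}/\code{alt}; point-mutation observations are rows with
#' \code{snp_index} 0 and allele \code{wt}/\code{mut}.
#'
#' @param reads a \code{barcoded_read_set}.
#' @param path output path.
#' @param mutation_pos position written for mutation-observation rows.
#' @return \code{path}, invisibly.
#' @export
write_reads_tsv <- function(reads, path, mutation_pos = NA) {
  obs <- reads$observations
  lines <- paste(obs$barcode, obs$snp, reads$snp_pos[obs$snp],
                 ifelse(obs$allele == 1L, "alt", "ref"), sep = "\t")
  mo <- reads$mutation_obs
  if (!is.null(mo) && nrow(mo)) {
    lines <- c(lines, paste(mo$barcode, 0L,
                            format(mutation_pos, scientific = FALSE, trim = TRUE),
                            ifelse(mo$allele == 1L, "mut", "wt"), sep = "\t"))
  }
  writeLines(c("barcode\tsnp_index\tpos\tallele", lines), path)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @param snp_pos SNP positions of the underlying SNP table; inferred
#'   from the file when omitted (requires every SNP observed).
#' @param params a \code{\link{sim_params}} to attach (molecule scale is
#'   needed by deletion linkage).
#' @return for the reader: a \code{barcoded_read_set} (without molecule
#'   truth).
#' @export
read_reads_tsv <- function(path, snp_pos = NULL, params = sim_params()) {
  lines <- .read_lines_checked(path)
  if (!length(lines) || lines[1L] != "barcode\tsnp_index\tpos\tallele") {
    stop_hapdose("%s: line 1: expected header 'barcode\\tsnp_index\\tpos\\tallele'", path)
  }
  body <- lines[-1L]
  fields <- .split_tsv(body, 4L, path, skip = 1L)
  barcode <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  snp <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  allele_s <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(barcode) | is.na(snp) |
                 !allele_s %in% c("ref", "alt", "wt", "mut"))
  if (length(bad)) stop_hapdose("%s: line %d: malformed record", path, bad[1L] + 1L)
  is_mut <- snp == 0L
  if (is.null(snp_pos)) {
    snp_pos <- rep(NA_real_, max(snp, 0L))
    snp_pos[snp[!is_mut]] <- pos[!is_mut]
    if (anyNA(snp_pos)) {
      stop_hapdose("%s: snp_pos not derivable (unobserved SNP indices); pass snp_pos", path)
    }
  }
  structure(list(observations = data.frame(
    barcode = barcode[!is_mut], snp = snp[!is_mut],
    allele = as.integer(allele_s[!is_mut] == "alt")),
    mutation_obs = data.frame(barcode = barcode[is_mut],
                              allele = as.integer(allele_s[is_mut] == "mut")),
    molecule_truth = NULL, snp_pos = snp_pos, params = params),
    class = "barcoded_read_set")
}

#' Write/read plasma allelic depths as TSV
#'
#' Dialect: header line, then \code{pos<TAB>ref_count<TAB>alt_count};
#' \code{pos} 0-based.
#'
#' @param counts a \code{plasma_counts} data.frame.
#' @param path file path.
#' @return \code{path} invisibly (writer); a plain
#'   \code{plasma_counts} data.frame without truth (reader).
#' @export
write_plasma_tsv <- function(counts, path) {
  writeLines(c("pos\tref_count\talt_count",
               paste(format(counts$pos, scientific = FALSE, trim = TRUE),
                     counts$ref_count, counts$alt_count, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_plasma_tsv
#' @export
read_plasma_tsv <- function(path) {
  lines <- .read_lines_checked(path)
  if (!length(lines) || lines[1L] != "pos\tref_count\talt_count") {
    stop_hapdose("%s: line 1: expected header 'pos\\tref_count\\talt_count'", path)
  }
  fields <- .split_tsv(lines[-1L], 3L, path, skip = 1L)
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  a <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  b <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(pos) | is.na(a) | is.na(b) | a < 0 | b < 0)
  if (length(bad)) stop_hapdose("%s: line %d: malformed record", path, bad[1L] + 1L)
  structure(data.frame(pos = pos, ref_count = a, alt_count = b),
            class = c("plasma_counts", "data.frame"))
}

#' Write/read the SV mutation as BED (+ type column)
#'
#' Columns: chrom, start, end (0-based half-open), kind, description.
#'
#' @param mutation an \code{\link{sv_mutation}}.
#' @param path file path.
#' @param chrom chromosome label.
#' @return \code{path} invisibly (writer); list with \code{mutation}
#'   and \code{chrom} (reader).
#' @export
write_sv_bed <- function(mutation, path, chrom = "chrX") {
  writeLines(paste(chrom,
                   format(mutation$start, scientific = FALSE, trim = TRUE),
                   format(mutation$end, scientific = FALSE, trim = TRUE),
                   mutation$kind, mutation$description, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_sv_bed
#' @export
read_sv_bed <- function(path) {
  lines <- .read_lines_checked(path)
  fields <- .split_tsv(lines, 4L, path)
  f <- fields[[1L]]
  start <- as.numeric(f[2L]); end <- as.numeric(f[3L])
  if (is.na(start) || is.na(end)) stop_hapdose("%s: line 1: malformed coordinates", path)
  list(mutation = sv_mutation(f[4L], start, end,
                              description = if (length(f) >= 5L) f[5L] else ""),
       chrom = f[1L])
}

#' Write a report (or truth record) as JSON
#'
#' @param x a list-like report.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a JSON family-config file into simulation configs
#'
#' Expected structure: a JSON array of family objects with fields
#' \code{name}, \code{mutation} (\code{kind}, \code{start}, \code{end},
#' optional \code{description}), \code{draws} (array of
#' \code{fetal_fraction}, \code{transmitted}, optional
#' \code{recomb_breakpoints}, \code{depth_per_snp}), optional
#' \code{region} (\code{chrom}, \code{start}, \code{end},
#' \code{n_snps}) and optional \code{params} (any
#' \code{\link{sim_params}} field).
#'
#' @param path JSON path.
#' @return list of validated family configs.
#' @export
config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(fc) {
    mut <- fc$mutation
    if (is.null(mut)) stop_hapdose("config %s: missing field 'mutation'", fc$name %||% "?")
    m <- sv_mutation(mut$kind, mut$start,
                     mut$end %||% (mut$start + 1), mut$description %||% "")
    reg <- if (is.null(fc$region)) region_spec() else
      region_spec(fc$region$chrom %||% "chrX", fc$region$start %||% 31100000,
                  fc$region$end %||% 33300000, fc$region$n_snps %||% 850)
    prm <- do.call(sim_params, fc$params %||% list())
    draws <- lapply(fc$draws %||% list(), function(d) {
      list(fetal_fraction = d$fetal_fraction, transmitted = d$transmitted,
           recomb_breakpoints = unlist(d$recomb_breakpoints) %||% integer(),
           depth_per_snp = d$depth_per_snp %||% 200L)
    })
    family_config(fc$name %||% "family", m, draws, region = reg, params = prm,
                  seed = fc$seed %||% 1L)
  })
}
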