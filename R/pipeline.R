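#' Analyse one simulated (or assembled) family dataset
#'
#' Runs the maternal phasing, the SV-to-haplotype linkage (for deletion
#' and duplication mutations) and the RHDO dosage analysis of every
#' plasma draw, and — when the dataset carries a simulation truth
#' record — scores calls and phasing against it.
#'
#' @param dataset a \code{family_dataset} from
#'   \code{\link{simulate_family}}, or a compatible list with
#'   \code{reads}, \code{plasma} and a \code{config} holding the
#'   mutation.
#' @param min_support,min_ratio phase-graph edge thresholds.
#' @param alpha significance level for recombination confirmation and
#'   the dosage call.
#' @param n_sigma outlier control-limit multiplier.
#' @param min_seg minimum changepoint segment length.
#' @param af_low,af_high divergent allele-fraction band for duplication
#'   linkage.
#' @return a \code{family_report}: list with \code{name}, \code{pair},
#'   \code{sv_linkage}, \code{n50}, \code{phasing} (concordance vs
#'   truth, if available) and \code{draws} (one \code{rhdo} summary per
#'   plasma draw, with truth comparison if available).
#' @export
analyze_family <- function(dataset, min_support = 2L, min_ratio = 0.75,
                           alpha = 0.01, n_sigma = 3, min_seg = 10L,
                           af_low = 0.4, af_high = 0.6) {
  mutation <- dataset$config$mutation
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_hapdose("[%s/%s] %s", dataset$name %||% "family", name,
                   conditionMessage(e))
    })
  }
  pair <- stage("phase", phase_linked_reads(dataset$reads, mutation,
                                            min_support = min_support,
                                            min_ratio = min_ratio))
  svres <- switch(mutation$kind,
                  deletion = stage("sv-link", link_deletion(dataset$reads, mutation, pair)),
                  duplication = stage("sv-link", link_duplication(dataset$reads, mutation, pair,
                                                                  af_low = af_low,
                                                                  af_high = af_high)),
                  NULL)
  # if the SV evidence contradicts the anchoring, the anchoring is wrong
  if (!is.null(svres) && !svres$is_hapA) {
    warning(sprintf("%s: SV linkage points to HapB; flipping HapA/HapB labels",
                    dataset$name %||% "family"))
    pair$hapA <- 1L - pair$hapA
    pair$hapB <- 1L - pair$hapB
  }
  n50 <- stage("phase", n50_phase_block(pair$blocks))
  phasing <- NULL
  if (!is.null(dataset$truth$hapA)) {
    phasing <- stage("phase", phasing_concordance(pair, dataset$truth$hapA))
  }
  draws <- lapply(seq_along(dataset$plasma %||% list()), function(k) {
    fit <- stage(sprintf("nipd/draw%d", k),
                 rhdo(dataset$plasma[[k]], pair, alpha = alpha,
                      n_sigma = n_sigma, min_seg = min_seg,
                      mutation_pos = mutation$start))
    out <- list(draw = k, call = fit$call,
                mean_fraction = fit$mean_fraction,
                p_value = fit$p_value,
                fetal_fraction = fit$fetal_fraction,
                recombination_detected = fit$recombination_detected,
                recomb_breakpoints = fit$recomb_breakpoints,
                qc = fit$qc, fit = fit)
    if (!is.null(dataset$truth$draws)) {
      tr <- dataset$truth$draws[[k]]
      out$truth_call <- tr$call
      out$truth_fetal_fraction <- tr$fetal_fraction
      out$truth_recombination <- tr$recombination
      out$correct <- identical(out$call, tr$call)
    }
    out
  })
  structure(list(name = dataset$name %||% "family",
                 mutation = mutation,
                 pair = pair, sv_linkage = svres, n50 = n50,
                 phasing = phasing, draws = draws),
            class = "family_report")
}

#' @export
print.family_report <- function(x, ...) {
  cat(sprintf("<family_report> %s (%s): N50 %.1f kb%s\n", x$name,
              x$mutation$kind, x$n50 / 1e3,
              if (!is.null(x$phasing))
                sprintf(", phasing concordance %.1f%%", 100 * x$phasing$concordance)
              else ""))
  for (d in x$draws) {
    cat(sprintf("  draw %d: %s (f-hat %.2f%%%s)%s\n", d$draw, d$call,
                100 * d$fetal_fraction,
                if (d$recombination_detected) ", recombination" else "",
                if (!is.null(d$correct))
                  if (d$correct) " [correct]" else " [WRONG]"
                else ""))
  }
  invisible(x)
}

# strip non-serializable payloads for the JSON report
.report_payload <- function(rep) {
  list(name = rep$name,
       mutation = list(kind = rep$mutation$kind, start = rep$mutation$start,
                       end = rep$mutation$end,
                       description = rep$mutation$description),
       n50_bp = rep$n50,
       sv_linkage = if (!is.null(rep$sv_linkage)) list(
         strand = rep$sv_linkage$strand,
         confidence = rep$sv_linkage$confidence,
         flank_check = rep$sv_linkage$flank_check,
         n_mutant_barcodes = rep$sv_linkage$n_mutant,
         n_wildtype_barcodes = rep$sv_linkage$n_wildtype),
       phasing = if (!is.null(rep$phasing)) rep$phasing,
       draws = lapply(rep$draws, function(d) {
         d$fit <- NULL
         d
       }))
}

#' Run the full simulate-phase-link-dose pipeline
#'
#' Simulates every configured family, analyses it end to end and
#' (optionally) writes one JSON report per family plus a run-level
#' summary with provenance (seed, config hash, package version) into
#' \code{outdir}. Identical config + seed reproduce byte-identical
#' reports.
#'
#' @param configs list of family configs (e.g. \code{\link{dmd_cohort}()}
#'   or \code{\link{config_from_json}}).
#' @param seed integer run seed, fanned out per family and stage.
#' @param outdir optional output directory (created if missing).
#' @param quiet suppress progress messages.
#' @param ... tunables forwarded to \code{\link{analyze_family}}.
#' @return an \code{nipd_run}: list with \code{reports},
#'   \code{datasets}, \code{seed} and \code{outdir}.
#' @export
run_pipeline <- function(configs, seed = 1L, outdir = NULL, quiet = FALSE,
                         ...) {
  if (!length(configs)) {
    warning("run_pipeline: no families configured; empty run")
    return(structure(list(reports = list(), datasets = list(),
                          seed = seed, outdir = outdir),
                     class = "nipd_run"))
  }
  configs <- lapply(configs, validate_family_config)
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  reports <- list()
  datasets <- list()
  for (k in seq_along(configs)) {
    cfg <- configs[[k]]
    if (!quiet) message(sprintf("[hapdose] family %s (%d/%d)", cfg$name, k,
                                length(configs)))
    ds <- simulate_family(cfg, seed = stage_seed(seed, paste0("family/", cfg$name)))
    rep <- analyze_family(ds, ...)
    datasets[[cfg$name]] <- ds
    reports[[cfg$name]] <- rep
    if (!is.null(outdir)) {
      payload <- .report_payload(rep)
      payload$provenance <- list(
        seed = seed,
        config_hash = config_hash(jsonlite::toJSON(
          lapply(cfg, function(z) if (is.list(z)) unclass(z) else z),
          auto_unbox = TRUE, digits = 10, force = TRUE)),
        package = "hapdose",
        version = as.character(utils::packageVersion("hapdose")))
      write_report_json(payload, file.path(outdir, paste0(cfg$name, ".json")))
    }
  }
  run <- structure(list(reports = reports, datasets = datasets, seed = seed,
                        outdir = outdir),
                   class = "nipd_run")
  if (!is.null(outdir)) {
    write_report_json(list(
      families = names(reports),
      n_draws = sum(vapply(reports, function(r) length(r$draws), 1L)),
      seed = seed,
      calls_correct = sum(vapply(reports, function(r) {
        sum(vapply(r$draws, function(d) isTRUE(d$correct), TRUE))
      }, 1L))),
      file.path(outdir, "run_summary.json"))
  }
  run
}

#' @export
print.nipd_run <- function(x, ...) {
  cat(sprintf("<nipd_run> %d families, seed %s\n", length(x$reports), x$seed))
  for (r in x$reports) print(r)
  invisible(x)
}

#' Per-draw result table of a pipeline run
#'
#' @param run an \code{nipd_run}.
#' @return data.frame with one row per plasma draw.
#' @export
report_table <- function(run) {
  stopifnot(inherits(run, "nipd_run"))
  rows <- list()
  for (r in run$reports) {
    for (d in r$draws) {
      rows[[length(rows) + 1L]] <- data.frame(
        family = r$name, draw = d$draw, call = d$call,
        truth_call = d$truth_call %||% NA_character_,
        correct = d$correct %||% NA,
        fetal_fraction = d$fetal_fraction,
        truth_fetal_fraction = d$truth_fetal_fraction %||% NA_real_,
        recombination = d$recombination_detected,
        concordance = if (!is.null(r$phasing)) r$phasing$concordance else NA_real_,
        n50_kb = r$n50 / 1e3)
    }
  }
  do.call(rbind, rows)
}
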