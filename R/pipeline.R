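# Pipeline orchestration: run the analysis stages in dependency order from a
# single config (R list or YAML file), collect a machine-readable report,
# and render a one-page text summary following the locus -> PAS call ->
# expression -> activity -> survival logic chain.

#' Default pipeline configuration
#'
#' Runs every stage on simulated inputs (the locus stage on the simulated
#' two-genotype locus, the remaining stages on their stage generators'
#' defaults).
#'
#' @param out_dir Output directory for generated files and reports.
#' @param seed Master seed; per-stage streams are derived via [stage_seed()].
#' @param stages Character vector of stages to run, in
#'   c("simulate", "locus", "scan", "quant", "enzyme", "survival").
#' @return Config list for [run_pipeline()].
#' @export
pipeline_config <- function(out_dir = tempfile("apaTE_run_"), seed = 1L,
                            stages = c("simulate", "locus", "scan", "quant",
                                       "enzyme", "survival")) {
  list(out_dir = out_dir, seed = seed, stages = stages,
       locus = locus_config(), qpcr = qpcr_config(),
       kinetics = kinetics_config(), acute = acute_config(),
       chronic = chronic_config(),
       max_pas_cs_span = 40L, log_level = "info")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order and returns a report
#' whose values regenerate every figure-level number: locus structural
#' quantities (3'UTR lengths, transcript lengths, antisense overlaps,
#' PAS-TE-CS distances), PAS/DSE annotation and insertion-effect calls,
#' qPCR isoform fractions and genotype folds, Michaelis-Menten fits with the
#' lack-of-fit test, and acute/chronic survival statistics. The report is
#' also written as JSON under `out_dir`.
#'
#' @param config A [pipeline_config()] list or path to a YAML file with the
#'   same structure (scalar fields only; stage blocks are merged over the
#'   defaults).
#' @return List of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config error: file not found: ", config)
    user <- yaml::read_yaml(config)
    config <- utils::modifyList(pipeline_config(), user)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), warnings = character(),
                 provenance = list(seed = config$seed,
                                   stages = config$stages,
                                   package_version =
                                     as.character(utils::packageVersion("apaTE")),
                                   timestamp = format(Sys.time(), tz = "UTC")))
  stages <- config$stages

  sim <- NULL
  if ("simulate" %in% stages || any(c("locus", "scan") %in% stages)) {
    sim <- simulate_locus(file.path(config$out_dir, "locus"),
                          stage_seed(config$seed, "locus"), config$locus)
    report$stages$simulate <- list(files = c(sim$without, sim$with))
  }

  if ("locus" %in% stages) {
    wo <- sim$loci$without_TE; wi <- sim$loci$with_TE
    isos <- locus_isoforms(wo)
    isos_wi <- locus_isoforms(wi)
    a <- config$locus$geneA; b <- config$locus$geneB
    short <- isos[[paste0(a$gene_id, "-short")]]
    long <- isos[[paste0(a$gene_id, "-long")]]
    bmain <- isos[[paste0(b$gene_id, "-main")]]
    bmain_wi <- isos_wi[[paste0(b$gene_id, "-main")]]
    ins <- wi$insertions[[1]]
    ctx <- insertion_context(ins, pas_end = a$pas_distal[2], cs = long$cleavage_site)
    report$stages$locus <- list(
      utr3 = c(short = utr3_length(short), long = utr3_length(long),
               antisense_main = utr3_length(bmain),
               antisense_short_utr =
                 utr3_length(isos[[paste0(b$gene_id, "-shortUTR")]])),
      transcript_length = c(antisense_without = transcript_length(bmain),
                            antisense_with = transcript_length(bmain_wi)),
      transcript_length_diff = transcript_length(bmain_wi) -
        transcript_length(bmain),
      overlap = c(without_TE = antisense_overlap(long, bmain),
                  with_TE = antisense_overlap(isos_wi[[paste0(a$gene_id, "-short")]],
                                              bmain_wi)),
      insertion_context = ctx)
  }

  if ("scan" %in% stages) {
    wo <- sim$loci$without_TE
    a <- config$locus$geneA
    pas <- build_pssm(default_pas_matrix())
    dse <- build_pssm(default_dse_matrix())
    ann_prox <- annotate_cleavage_site(wo$sequence, a$cs_short, pas, dse)
    ann_dist <- annotate_cleavage_site(wo$sequence, a$cs_long, pas, dse)
    cmp <- compare_pas_strength(ann_prox, ann_dist)
    ins <- te_insertion(config$locus$after_base, config$locus$te_length,
                        config$locus$tsd_length)
    call_dist <- predict_insertion_effect(cmp$distal, ins,
                                          config$max_pas_cs_span)
    call_prox <- predict_insertion_effect(cmp$proximal, ins,
                                          config$max_pas_cs_span)
    report$stages$scan <- list(
      proximal = cmp$proximal[c("cs", "pas", "dse", "strength_label")],
      distal = cmp$distal[c("cs", "pas", "dse", "strength_label")],
      ordering = cmp$ordering,
      usage_calls = list(proximal = unclass(call_prox),
                         distal = unclass(call_dist)))
  }

  if ("quant" %in% stages) {
    qd <- simulate_qpcr(stage_seed(config$seed, "qpcr"), config$qpcr,
                        path = file.path(config$out_dir, "qpcr.tsv"))
    qa <- quantify_experiment(qd)
    report$stages$quant <- list(
      efficiencies = vapply(qa$curves, function(c) c$efficiency, numeric(1)),
      fractions = qa$fractions,
      folds = lapply(qa$folds, function(f) f[c("fold", "p")]))
  }

  if ("enzyme" %in% stages) {
    kd <- simulate_kinetics(stage_seed(config$seed, "kinetics"),
                            config$kinetics,
                            path = file.path(config$out_dir, "kinetics.tsv"))
    fits <- lapply(split(kd, kd$genotype), function(d) {
      f <- fit_michaelis_menten(d)
      list(vmax = f$vmax, vmax_ci = f$vmax_ci, km = f$km,
           lack_of_fit = lack_of_fit_test(f)[c("F", "p")])
    })
    report$stages$enzyme <- fits
  }

  if ("survival" %in% stages) {
    ad <- simulate_acute(stage_seed(config$seed, "acute"), config$acute,
                         path = file.path(config$out_dir, "acute.tsv"))
    acute_out <- list()
    for (sex in unique(ad$sex)) {
      d <- ad[ad$sex == sex & ad$condition == "stressed", ]
      tab <- acute_table(d)
      orr <- odds_ratio(tab)
      props <- split(1 - d$n_dead / d$n_start, d$genotype)
      pt <- proportion_test(props$with_TE, props$without_TE, "t")
      acute_out[[sex]] <- list(or = orr$or, ci = orr$ci, t_p = pt$p,
                               design_total = design_total(
                                 nrow(d) / 2, d$n_start[1], 1, 2, 1))
    }
    cd <- simulate_chronic(stage_seed(config$seed, "chronic"), config$chronic,
                           path = file.path(config$out_dir, "chronic.tsv"))
    chron_out <- list()
    for (sex in unique(cd$sex)) {
      d <- cd[cd$sex == sex, ]
      cmp <- compare_survival(d[d$genotype == "with_TE", ],
                              d[d$genotype == "without_TE", ],
                              config$chronic$flies_per_replica)
      chron_out[[sex]] <- list(logrank_chi2 = cmp$logrank_chi2,
                               logrank_p = cmp$logrank_p,
                               or = cmp$odds_ratio, ci = cmp$or_ci,
                               census_time_h = cmp$census_time_h)
    }
    report$stages$survival <- list(acute = acute_out, chronic = chron_out)
  }

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  report
}

#' One-page text summary of a pipeline report
#'
#' Mirrors the causal chain of the analysis: locus architecture, PAS usage
#' call, expression, enzyme activity, survival.
#'
#' @param report A [run_pipeline()] result.
#' @return Character vector of lines (also printable via `cat`).
#' @export
report_summary <- function(report) {
  if (!length(report$stages)) return("no stages run")
  out <- character()
  add <- function(...) out <<- c(out, sprintf(...))
  s <- report$stages
  if (!is.null(s$locus)) {
    add("Locus: 3'UTRs %d/%d bp (short/long), antisense overlap %d bp without TE vs %d bp with TE; TE lengthens the antisense transcript by %d bp.",
        s$locus$utr3[["short"]], s$locus$utr3[["long"]],
        s$locus$overlap[["without_TE"]], s$locus$overlap[["with_TE"]],
        s$locus$transcript_length_diff)
    if (isTRUE(s$locus$insertion_context$between))
      add("TE sits %d bp downstream of the distal PAS and %d bp upstream of the distal cleavage site.",
          s$locus$insertion_context$bp_pas_to_te,
          s$locus$insertion_context$bp_te_to_cs)
  }
  if (!is.null(s$scan)) {
    add("PAS scan: proximal %s (%.2f bits), distal %s (%.2f bits) -> %s.",
        s$scan$proximal$strength_label, s$scan$proximal$pas$score,
        s$scan$distal$strength_label, s$scan$distal$pas$score,
        s$scan$ordering)
    dc <- s$scan$usage_calls$distal
    add("With the TE, the distal cleavage site is %s (%s; PAS-to-CS span %d bp).",
        if (dc$usable) "usable" else "not usable", dc$reason,
        dc$pas_cs_distance)
  }
  if (!is.null(s$quant)) {
    fr <- s$quant$fractions
    wo <- fr$fraction_long[fr$genotype == "without_TE"]
    add("Expression: long-isoform fraction %.1f%% without TE; total-expression fold (with/without): %s.",
        100 * mean(wo),
        paste(sprintf("%s %.2f (p=%s)", names(s$quant$folds),
                      vapply(s$quant$folds, function(f) f$fold, numeric(1)),
                      vapply(s$quant$folds, function(f)
                        format(f$p, digits = 3), character(1))),
              collapse = ", "))
  }
  if (!is.null(s$enzyme)) {
    add("Enzyme activity: %s.",
        paste(sprintf("%s Vmax %.2f (%.2f-%.2f)", names(s$enzyme),
                      vapply(s$enzyme, function(f) f$vmax, numeric(1)),
                      vapply(s$enzyme, function(f) f$vmax_ci[1], numeric(1)),
                      vapply(s$enzyme, function(f) f$vmax_ci[2], numeric(1))),
              collapse = "; "))
  }
  if (!is.null(s$survival)) {
    for (sex in names(s$survival$acute)) {
      a <- s$survival$acute[[sex]]
      add("Acute survival (%s): OR %.2f (%.2f-%.2f), t-test p = %s.",
          sex, a$or, a$ci[1], a$ci[2], format(a$t_p, digits = 3))
    }
    for (sex in names(s$survival$chronic)) {
      ch <- s$survival$chronic[[sex]]
      add("Chronic survival (%s): log-rank chi2 = %.2f, p = %s; OR %.2f (%.2f-%.2f) at %g h.",
          sex, ch$logrank_chi2, format(ch$logrank_p, digits = 3),
          ch$or, ch$ci[1], ch$ci[2], ch$census_time_h)
    }
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(report_summary(x), sep = "\n")
  invisible(x)
}
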