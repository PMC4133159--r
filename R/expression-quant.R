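# Standard-curve qPCR quantification: per-amplicon dilution curves with
# efficiency correction, absolute copy quantification, per-sample
# normalization to a reference gene, isoform decomposition (short vs long
# 3'UTR) and genotype fold change.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10 copies over a dilution series.
#' Amplification efficiency is `10^(-1/slope) - 1` (1 = 100%).
#'
#' @param ds Data frame with columns `log10_copies` and `cq` (replicates
#'   allowed), or a list with those elements.
#' @param amplicon_id Identifier attached to the curve.
#' @return An object of class `standard_curve`: `slope`, `intercept`, `r2`,
#'   `efficiency`, `amplicon_id`, `n_dilutions`.
#' @export
fit_standard_curve <- function(ds, amplicon_id = NA_character_) {
  ds <- as.data.frame(ds)
  if (length(unique(ds$log10_copies)) < 3L)
    stop("need >= 3 distinct dilutions to fit a standard curve")
  fit <- lm(cq ~ log10_copies, data = ds)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("curve failure: non-negative slope (", format(slope), ")")
  sst <- sum((ds$cq - mean(ds$cq))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(amplicon_id = amplicon_id, slope = slope,
                 intercept = unname(coef(fit)[1]), r2 = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 n_dilutions = length(unique(ds$log10_copies))),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve [%s]: Cq = %.4f + %.4f*log10(copies), r2 = %.4f, efficiency = %.1f%%\n",
              x$amplicon_id, x$intercept, x$slope, x$r2, 100 * x$efficiency))
  invisible(x)
}

#' Predicted Cq for a copy number under a standard curve
#' @param curve A [fit_standard_curve()] result.
#' @param copies Copy number (> 0).
#' @return Cq value(s).
#' @export
predict_cq <- function(curve, copies) curve$intercept + curve$slope * log10(copies)

#' Copy number from an observed Cq under a standard curve
#' @param cq Observed quantification cycle(s).
#' @param curve A [fit_standard_curve()] result.
#' @return Copies, `10^((cq - intercept)/slope)`.
#' @export
quantify <- function(cq, curve) 10^((cq - curve$intercept) / curve$slope)

#' Decompose total expression into short- and long-3'UTR isoforms
#'
#' The total amplicon counts both isoforms; the long amplicon only the long
#' one. `copies_short = copies_total - copies_long`, clipped at 0 (with a
#' warning and flag) when noise puts the long amplicon above the total.
#'
#' @param copies_total,copies_long Copy numbers (total > 0).
#' @return List: `copies_short`, `fraction_long` (in \[0, 1\]), `clipped`.
#' @export
isoform_decomposition <- function(copies_total, copies_long) {
  if (any(copies_total <= 0)) stop("copies_total must be > 0")
  clipped <- copies_long > copies_total
  if (any(clipped))
    warning("copies_long exceeds copies_total; short isoform clipped at 0")
  list(copies_short = pmax(copies_total - copies_long, 0),
       fraction_long = pmin(copies_long / copies_total, 1),
       clipped = clipped)
}

#' Fold change between two groups of normalized expression values
#'
#' Fold is the ratio of group means (`mean(groupA)/mean(groupB)`) by default;
#' the `"mean_of_ratios"` alternative averages per-replicate ratios for
#' groups paired by replicate index.
#' Significance is a two-sided Welch t test on the replicate values;
#' zero-variance input returns `p = NA` with `degenerate = TRUE` instead of
#' erroring (noise-free fixtures).
#'
#' @param groupA,groupB Numeric vectors of per-replicate normalized
#'   expression (>= 2 values each).
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"` (paired
#'   by index; requires equal lengths).
#' @return List: `fold`, `t`, `p`, `degenerate`.
#' @export
fold_change <- function(groupA, groupB,
                        method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("need >= 2 replicates per group")
  if (mean(groupB) == 0) stop("undefined fold: zero mean denominator")
  fold <- if (method == "ratio_of_means") mean(groupA) / mean(groupB)
  else {
    if (length(groupA) != length(groupB))
      stop("mean_of_ratios requires equal group sizes (paired replicates)")
    mean(groupA / groupB)
  }
  if (var(groupA) == 0 && var(groupB) == 0) {
    if (isTRUE(all.equal(mean(groupA), mean(groupB)))) {
      return(list(fold = fold, t = 0, p = 1, degenerate = TRUE))
    }
    return(list(fold = fold, t = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(fold = fold, t = unname(tt$statistic), p = tt$p.value,
       degenerate = FALSE)
}

#' Run the full qPCR quantification chain on a long-format table
#'
#' Expects one row per well with columns `sample_id`, `genotype`, `sex`,
#' `amplicon_id`, `dilution_log10_copies` (set for standards, `NA` for
#' unknowns) and `cq`. Per amplicon, fits a standard curve on the standards,
#' quantifies the unknowns, averages technical replicates per sample,
#' normalizes by the reference-gene copy number of the same sample, and
#' decomposes total vs long-isoform expression. Genotype fold changes on
#' normalized total expression are computed per sex
#' (`with_TE / without_TE`).
#'
#' @param data Data frame or path to a TSV in the layout above.
#' @param reference_amplicon,total_amplicon,long_amplicon Amplicon ids.
#' @param fold_method Passed to [fold_change()].
#' @return List of class `qpcr_analysis`: `curves`, `samples` (per-sample
#'   table with `copies_*`, `rel_total`, `rel_long`, `fraction_long`),
#'   `fractions` (mean fraction_long per genotype/sex), `folds` (per sex).
#' @export
quantify_experiment <- function(data, reference_amplicon = "Act5C",
                                total_amplicon = "total",
                                long_amplicon = "long",
                                fold_method = "ratio_of_means") {
  if (is.character(data) && length(data) == 1L)
    data <- read.delim(data, stringsAsFactors = FALSE)
  std <- data[!is.na(data$dilution_log10_copies), , drop = FALSE]
  unk <- data[is.na(data$dilution_log10_copies), , drop = FALSE]
  if (!nrow(std)) stop("no standards (dilution_log10_copies all NA)")
  curves <- lapply(split(std, std$amplicon_id), function(d)
    fit_standard_curve(data.frame(log10_copies = d$dilution_log10_copies,
                                  cq = d$cq), d$amplicon_id[1]))
  needed <- c(reference_amplicon, total_amplicon, long_amplicon)
  missing <- setdiff(needed, names(curves))
  if (length(missing))
    stop("no standard curve for amplicon(s): ", paste(missing, collapse = ", "))

  unk$copies <- NA_real_
  for (a in unique(unk$amplicon_id))
    unk$copies[unk$amplicon_id == a] <-
      quantify(unk$cq[unk$amplicon_id == a], curves[[a]])

  # mean over technical replicates per sample x amplicon
  agg <- stats::aggregate(copies ~ sample_id + genotype + sex + amplicon_id,
                          data = unk, FUN = mean)
  wide <- stats::reshape(agg, idvar = c("sample_id", "genotype", "sex"),
                         timevar = "amplicon_id", direction = "wide")
  names(wide) <- sub("^copies\\.", "copies_", names(wide))
  ref_col <- paste0("copies_", reference_amplicon)
  tot_col <- paste0("copies_", total_amplicon)
  long_col <- paste0("copies_", long_amplicon)
  wide$rel_total <- wide[[tot_col]] / wide[[ref_col]]
  wide$rel_long <- wide[[long_col]] / wide[[ref_col]]
  dec <- isoform_decomposition(wide[[tot_col]], wide[[long_col]])
  wide$copies_short <- dec$copies_short
  wide$fraction_long <- dec$fraction_long

  fractions <- stats::aggregate(fraction_long ~ genotype + sex, data = wide,
                                FUN = mean)
  folds <- lapply(split(wide, wide$sex), function(d) {
    a <- d$rel_total[d$genotype == "with_TE"]
    b <- d$rel_total[d$genotype == "without_TE"]
    if (length(a) >= 2L && length(b) >= 2L) fold_change(a, b, fold_method)
    else NULL
  })
  structure(list(curves = curves, samples = wide, fractions = fractions,
                 folds = Filter(Negate(is.null), folds)),
            class = "qpcr_analysis")
}

#' Write a qPCR analysis as per-sample TSV plus JSON summary
#'
#' @param qa A [quantify_experiment()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of paths (samples, summary).
#' @export
write_qpcr_results <- function(qa, dir, prefix = "qpcr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- file.path(dir, paste0(prefix, "_samples.tsv"))
  summary <- file.path(dir, paste0(prefix, "_summary.json"))
  write.table(qa$samples, samples, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(efficiencies = lapply(qa$curves, function(c)
      c[c("slope", "intercept", "r2", "efficiency")]),
      fractions = qa$fractions,
      folds = lapply(qa$folds, function(f) f[c("fold", "t", "p")])),
    summary, auto_unbox = TRUE, digits = NA, null = "null")
  c(samples = samples, summary = summary)
}
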