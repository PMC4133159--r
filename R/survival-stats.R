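# Acute-exposure statistics (pooled 2x2 odds ratios with Woolf CIs,
# replicate proportion tests) and chronic-exposure statistics (pooled
# product-limit survival curves, log-rank test), plus experimental-design
# accounting.

#' Pool acute-assay replicates into a 2x2 table
#'
#' Sums survivors and dead across replicates per genotype. All replicates
#' must share sex and condition. Cell layout: rows `with_TE` / `without_TE`,
#' columns `alive` / `dead`.
#'
#' @param replicates Data frame with columns `genotype`
#'   (`with_TE`/`without_TE`), `n_start`, `n_dead`, and optionally `sex`,
#'   `condition` (must each be single-valued).
#' @return 2x2 integer matrix of class `contingency_2x2`.
#' @export
acute_table <- function(replicates) {
  replicates <- as.data.frame(replicates)
  if (!nrow(replicates)) stop("empty replicate table")
  for (col in c("sex", "condition"))
    if (col %in% names(replicates) &&
        length(unique(replicates[[col]])) > 1L)
      stop("usage error: mixed ", col, " in acute_table input")
  if (any(replicates$n_dead < 0 | replicates$n_dead > replicates$n_start))
    stop("n_dead must lie in [0, n_start]")
  tab <- matrix(0L, 2, 2,
                dimnames = list(genotype = c("with_TE", "without_TE"),
                                outcome = c("alive", "dead")))
  for (g in rownames(tab)) {
    d <- replicates[replicates$genotype == g, , drop = FALSE]
    tab[g, "dead"] <- sum(d$n_dead)
    tab[g, "alive"] <- sum(d$n_start) - sum(d$n_dead)
  }
  structure(tab, class = c("contingency_2x2", "matrix"))
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a*d)/(b*c)` on the 2x2 table (a = with_TE alive, b = with_TE dead,
#' c = without_TE alive, d = without_TE dead). If any cell is zero, the
#' Haldane-Anscombe correction adds 0.5 to every cell (flagged). The CI is
#' the Woolf log interval `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param tab A 2x2 matrix (rows genotype, columns alive/dead), e.g. from
#'   [acute_table()].
#' @param conf_level Confidence level (default 0.95).
#' @return List: `or`, `ci` (length 2), `corrected`.
#' @export
odds_ratio <- function(tab, conf_level = 0.95) {
  tab <- unclass(as.matrix(tab))
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  corrected <- any(tab == 0)
  x <- tab + if (corrected) 0.5 else 0
  a <- x[1, 1]; b <- x[1, 2]; c_ <- x[2, 1]; d <- x[2, 2]
  or <- (a * d) / (b * c_)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se), corrected = corrected)
}

#' Mantel-Haenszel odds ratio across replicate strata
#'
#' @param tables List of 2x2 matrices (one per stratum/replicate).
#' @return The Mantel-Haenszel pooled odds ratio.
#' @export
mh_odds_ratio <- function(tables) {
  num <- den <- 0
  for (t in tables) {
    t <- unclass(as.matrix(t))
    n <- sum(t)
    num <- num + t[1, 1] * t[2, 2] / n
    den <- den + t[1, 2] * t[2, 1] / n
  }
  num / den
}

#' Compare per-replicate survival proportions between genotypes
#'
#' @param propsA,propsB Numeric vectors of per-replicate survival
#'   proportions.
#' @param method `"t"` (Welch, two-sided) or `"mannwhitney"` (two-sided
#'   Wilcoxon rank-sum; exact when no ties and small n).
#' @return List: `p`, `statistic`, `method`, `degenerate` (TRUE with
#'   `p = NA` when both groups have zero variance under the t test).
#' @export
proportion_test <- function(propsA, propsB, method = c("t", "mannwhitney")) {
  method <- match.arg(method)
  if (method == "t") {
    if (length(propsA) < 2L || length(propsB) < 2L)
      stop("t test needs >= 2 replicates per group")
    if (var(propsA) == 0 && var(propsB) == 0) {
      p <- if (isTRUE(all.equal(mean(propsA), mean(propsB)))) 1 else NA_real_
      return(list(p = p, statistic = NA_real_, method = method,
                  degenerate = TRUE))
    }
    tt <- stats::t.test(propsA, propsB, var.equal = FALSE)
    list(p = tt$p.value, statistic = unname(tt$statistic), method = method,
         degenerate = FALSE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(propsA, propsB))
    list(p = wt$p.value, statistic = unname(wt$statistic), method = method,
         degenerate = FALSE)
  }
}

# Expand interval death counts into per-individual event times. Survivors at
# the last observation are administratively censored there.
expand_death_records <- function(records, flies_per_replica) {
  records <- as.data.frame(records)
  out <- list()
  for (rid in unique(records$replicate_id)) {
    d <- records[records$replicate_id == rid, , drop = FALSE]
    d <- d[order(d$time_h), , drop = FALSE]
    if (any(d$n_dead_in_interval < 0))
      stop("data error: negative death count")
    total_dead <- sum(d$n_dead_in_interval)
    if (total_dead > flies_per_replica)
      stop("data error: deaths exceed replicate size in replicate ", rid)
    times <- rep(d$time_h, d$n_dead_in_interval)
    n_cens <- flies_per_replica - total_dead
    out[[length(out) + 1L]] <- data.frame(
      replicate_id = rid,
      time = c(times, rep(max(d$time_h), n_cens)),
      status = c(rep(1L, length(times)), rep(0L, n_cens)))
  }
  do.call(rbind, out)
}

#' Pooled product-limit (Kaplan-Meier) survival curve
#'
#' Pools interval death counts across replicates of one group and returns
#' the product-limit estimate over the observation times. Survivors at the
#' final observation are administratively censored; with no other censoring
#' the estimate equals `1 - cumulative_deaths/total`.
#'
#' @param records Data frame with columns `replicate_id`, `time_h`,
#'   `n_dead_in_interval` for a single group.
#' @param flies_per_replica Number of flies at risk per replicate at t = 0.
#' @return Data frame: `time`, `n_risk`, `n_event`, `surv` (step function,
#'   `S(0) = 1` implied).
#' @export
km_curve <- function(records, flies_per_replica) {
  ind <- expand_death_records(records, flies_per_replica)
  sf <- survival::survfit(survival::Surv(time, status) ~ 1, data = ind)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv)
}

#' Two-group log-rank test on interval death counts
#'
#' One-degree-of-freedom log-rank: `chi2 = (sum(O) - sum(E))^2 / sum(V)`,
#' p from chi-square(1). Counts are expanded to individual event times and
#' survivors censored at each replicate's final observation.
#'
#' @param recordsA,recordsB Death-record tables (see [km_curve()]) for the
#'   two groups.
#' @param flies_per_replica At-risk count per replicate (shared).
#' @return List: `chi2`, `p`, `available` (FALSE with NA statistics when
#'   there are no events).
#' @export
logrank <- function(recordsA, recordsB, flies_per_replica) {
  a <- expand_death_records(recordsA, flies_per_replica)
  b <- expand_death_records(recordsB, flies_per_replica)
  if (sum(a$status) + sum(b$status) == 0L)
    return(list(chi2 = NA_real_, p = NA_real_, available = FALSE))
  dat <- rbind(cbind(a, group = "A"), cbind(b, group = "B"))
  sd_ <- survival::survdiff(survival::Surv(time, status) ~ group, data = dat)
  list(chi2 = unname(sd_$chisq),
       p = pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       available = TRUE)
}

#' Compare two chronic-assay arms
#'
#' Kaplan-Meier curves, log-rank test, and an odds ratio of survival at a
#' census time. The census time defaults to the final common observation
#' time of the two arms; because the underlying census time for a published
#' OR is rarely stated, the chosen time is recorded in the output.
#'
#' @param recordsA,recordsB Death-record tables (see [km_curve()]), arm A
#'   conventionally `with_TE`.
#' @param flies_per_replica At-risk count per replicate.
#' @param census_time_h Census time for the odds ratio (default: last common
#'   observation time).
#' @return List of class `survival_comparison`: `curveA`, `curveB`,
#'   `logrank_chi2`, `logrank_p`, `odds_ratio`, `or_ci`, `census_time_h`.
#' @export
compare_survival <- function(recordsA, recordsB, flies_per_replica,
                             census_time_h = NULL) {
  if (is.null(census_time_h))
    census_time_h <- min(max(recordsA$time_h), max(recordsB$time_h))
  lr <- logrank(recordsA, recordsB, flies_per_replica)
  dead_at <- function(records) {
    d <- records[records$time_h <= census_time_h, , drop = FALSE]
    n_rep <- length(unique(records$replicate_id))
    c(dead = sum(d$n_dead_in_interval),
      alive = n_rep * flies_per_replica - sum(d$n_dead_in_interval))
  }
  a <- dead_at(recordsA); b <- dead_at(recordsB)
  tab <- matrix(c(a["alive"], a["dead"], b["alive"], b["dead"]), 2, 2,
                byrow = TRUE,
                dimnames = list(genotype = c("with_TE", "without_TE"),
                                outcome = c("alive", "dead")))
  orr <- odds_ratio(tab)
  structure(list(curveA = km_curve(recordsA, flies_per_replica),
                 curveB = km_curve(recordsB, flies_per_replica),
                 logrank_chi2 = lr$chi2, logrank_p = lr$p,
                 odds_ratio = orr$or, or_ci = orr$ci,
                 census_time_h = census_time_h,
                 census_note = "odds ratio censused at the final common observation time unless census_time_h was supplied"),
            class = "survival_comparison")
}

#' Total animals implied by a factorial assay design
#'
#' @param replicas_per_group,flies_per_replica,n_sexes,n_genotypes,n_conditions
#'   Positive integers (factors default to 1).
#' @return Product of all design factors.
#' @export
design_total <- function(replicas_per_group, flies_per_replica, n_sexes = 1L,
                         n_genotypes = 1L, n_conditions = 1L) {
  vals <- c(replicas_per_group, flies_per_replica, n_sexes, n_genotypes,
            n_conditions)
  if (any(vals < 1L) || any(vals != as.integer(vals)))
    stop("design factors must be positive integers")
  prod(vals)
}
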