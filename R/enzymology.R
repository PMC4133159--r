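# ALDH-III enzymology: initial reaction rates from A340 absorbance traces
# (NAD(P)H formation), per-mg protein normalization, Michaelis-Menten
# least-squares fit with asymptotic confidence intervals, and the replicates
# lack-of-fit F test.

#' Initial reaction rate from an absorbance trace
#'
#' Ordinary least-squares slope of absorbance (AU at 340 nm) on time
#' (minutes), converted to mOD/min and normalized by protein mass. Traces
#' whose linear fit has R-squared at or below the gate (default 0.98, as for
#' initial-rate validity) are flagged and should be excluded from kinetics.
#'
#' @param times Minutes, strictly increasing, >= 4 points.
#' @param od340 Absorbance units at 340 nm.
#' @param protein_mg Protein mass in mg (> 0).
#' @param substrate_mM Substrate concentration carried through to the result.
#' @param r2_gate R-squared threshold for trace linearity.
#' @param replicate_id Optional identifier.
#' @return List of class `rate_point`: `substrate_mM`, `rate`
#'   (mOD min^-1 mg^-1), `r2_of_slope`, `passes_gate`, `replicate_id`.
#' @export
initial_rate <- function(times, od340, protein_mg, substrate_mM = NA_real_,
                         r2_gate = 0.98, replicate_id = NA_character_) {
  if (length(times) < 4L) stop("insufficient data: need >= 4 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (protein_mg <= 0) stop("protein_mg must be > 0")
  fit <- lm(od340 ~ times)
  slope_au <- unname(coef(fit)[2])
  sst <- sum((od340 - mean(od340))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sst  # NaN for a flat trace
  passes <- is.finite(r2) && r2 > r2_gate
  structure(list(substrate_mM = substrate_mM,
                 rate = slope_au * 1000 / protein_mg,
                 r2_of_slope = r2, passes_gate = passes,
                 replicate_id = replicate_id),
            class = "rate_point")
}

#' Initial rates for a table of absorbance traces
#'
#' @param traces Data frame or TSV path with columns `sample_id`,
#'   `substrate_mM`, `minute`, `od340`, `protein_mg` (one row per reading);
#'   one trace per `sample_id` x `substrate_mM`.
#' @param r2_gate Passed to [initial_rate()].
#' @param drop_failing Drop traces failing the R-squared gate (default TRUE).
#' @return Data frame: `replicate_id`, `substrate_mM`, `rate`, `r2_of_slope`,
#'   `passes_gate`.
#' @export
initial_rates <- function(traces, r2_gate = 0.98, drop_failing = TRUE) {
  if (is.character(traces) && length(traces) == 1L)
    traces <- read.delim(traces, stringsAsFactors = FALSE)
  pieces <- split(traces, list(traces$sample_id, traces$substrate_mM),
                  drop = TRUE)
  out <- do.call(rbind, lapply(pieces, function(d) {
    rp <- initial_rate(d$minute, d$od340, d$protein_mg[1],
                       substrate_mM = d$substrate_mM[1],
                       r2_gate = r2_gate, replicate_id = d$sample_id[1])
    data.frame(replicate_id = rp$replicate_id, substrate_mM = rp$substrate_mM,
               rate = rp$rate, r2_of_slope = rp$r2_of_slope,
               passes_gate = rp$passes_gate, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (drop_failing) out <- out[out$passes_gate, , drop = FALSE]
  out
}

# Lineweaver-Burk seed: 1/v = (Km/Vmax) (1/S) + 1/Vmax on points with v > 0.
mm_start <- function(S, v) {
  ok <- v > 0 & S > 0
  if (sum(ok) >= 2L) {
    lb <- lm(I(1 / v[ok]) ~ I(1 / S[ok]))
    vmax0 <- 1 / coef(lb)[1]
    km0 <- coef(lb)[2] * vmax0
    if (is.finite(vmax0) && is.finite(km0) && vmax0 > 0 && km0 > 0)
      return(c(Vmax = unname(vmax0), Km = unname(km0)))
  }
  c(Vmax = max(v) * 1.2 + 1e-9, Km = stats::median(S))
}

#' Fit the Michaelis-Menten equation by least squares
#'
#' Minimizes `sum((v - Vmax*S/(Km + S))^2)` with a Levenberg-Marquardt
#' optimizer seeded from a Lineweaver-Burk regression (with a grid multistart
#' fallback). Reports asymptotic 95% confidence intervals from the
#' linearized covariance at the optimum (estimate +/- t(df, 0.975) * SE),
#' the convention of standard curve-fitting tools.
#'
#' @param points Data frame with columns `substrate_mM` and `rate`
#'   (replicates as repeated rows), e.g. from [initial_rates()].
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `kinetics_fit`: `vmax`, `vmax_ci`, `km`, `km_ci`,
#'   `sse`, `df`, `boundary` (TRUE when all rates are 0), `fit` (the nls
#'   object), `points`.
#' @export
fit_michaelis_menten <- function(points, conf_level = 0.95) {
  points <- as.data.frame(points)
  S <- points$substrate_mM
  v <- points$rate
  if (length(unique(S)) < 2L)
    stop("need >= 2 distinct substrate concentrations")
  if (all(v == 0)) {
    return(structure(list(vmax = 0, vmax_ci = c(0, 0), km = NA_real_,
                          km_ci = c(NA_real_, NA_real_), sse = 0,
                          df = length(v) - 2L, boundary = TRUE, fit = NULL,
                          points = points),
                     class = "kinetics_fit"))
  }
  start <- mm_start(S, v)
  dat <- data.frame(S = S, v = v)
  try_fit <- function(st) tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = dat, start = as.list(st),
                      lower = c(Vmax = 0, Km = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fit <- try_fit(start)
  if (is.null(fit)) {
    grid <- expand.grid(Vmax = max(v) * c(0.5, 1, 2, 5),
                        Km = unname(stats::quantile(S, c(0.1, 0.5, 0.9))))
    for (i in seq_len(nrow(grid))) {
      fit <- try_fit(c(Vmax = grid$Vmax[i], Km = grid$Km[i]))
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) stop("fit failure: Michaelis-Menten least squares did not converge")
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  df <- length(v) - 2L
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  structure(list(
    vmax = unname(est["Vmax"]),
    vmax_ci = unname(est["Vmax"] + c(-1, 1) * tcrit * se["Vmax"]),
    km = unname(est["Km"]),
    km_ci = unname(est["Km"] + c(-1, 1) * tcrit * se["Km"]),
    sse = sum(stats::residuals(fit)^2), df = df, boundary = FALSE, fit = fit,
    points = points), class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Vmax = %.3f (%.3f to %.3f), Km = %.4g (%.4g to %.4g), SSE = %.4g\n",
              x$vmax, x$vmax_ci[1], x$vmax_ci[2], x$km, x$km_ci[1], x$km_ci[2],
              x$sse))
  invisible(x)
}

#' Predicted Michaelis-Menten rate
#' @param fit A [fit_michaelis_menten()] result.
#' @param S Substrate concentrations (mM).
#' @return Predicted rates.
#' @export
predict_mm <- function(fit, S) fit$vmax * S / (fit$km + S)

#' Replicates lack-of-fit test for a kinetics fit
#'
#' Partitions the residual sum of squares into pure error (within replicated
#' concentrations) and lack of fit:
#' `F = (SS_lof / df_lof) / (SS_pe / df_pe)` with an upper-tail p from the F
#' distribution. A small p rejects the Michaelis-Menten mean function.
#'
#' @param fit A [fit_michaelis_menten()] result (its `points` carry the
#'   replicate structure).
#' @return List: `F`, `p`, `ss_lof`, `ss_pe`, `df_lof`, `df_pe`, `available`.
#' @export
lack_of_fit_test <- function(fit) {
  pts <- fit$points
  groups <- split(pts$rate, pts$substrate_mM)
  if (!any(vapply(groups, length, integer(1)) >= 2L))
    return(list(F = NA_real_, p = NA_real_, ss_lof = NA_real_,
                ss_pe = NA_real_, df_lof = NA_integer_, df_pe = NA_integer_,
                available = FALSE))
  ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  sse <- sum((pts$rate - predict_mm(fit, pts$substrate_mM))^2)
  ss_lof <- max(sse - ss_pe, 0)
  n <- nrow(pts); m <- length(groups); p_par <- 2L
  df_pe <- n - m
  df_lof <- m - p_par
  if (df_lof <= 0L || df_pe <= 0L)
    return(list(F = NA_real_, p = NA_real_, ss_lof = ss_lof, ss_pe = ss_pe,
                df_lof = df_lof, df_pe = df_pe, available = FALSE))
  if (ss_lof <= 1e-12 * max(sse, 1e-300)) {
    # replicate means sit on the fitted curve (saturated fit): no lack of fit
    return(list(F = 0, p = 1, ss_lof = ss_lof, ss_pe = ss_pe,
                df_lof = df_lof, df_pe = df_pe, available = TRUE))
  }
  Fstat <- (ss_lof / df_lof) / (ss_pe / df_pe)
  list(F = Fstat, p = pf(Fstat, df_lof, df_pe, lower.tail = FALSE),
       ss_lof = ss_lof, ss_pe = ss_pe, df_lof = df_lof, df_pe = df_pe,
       available = TRUE)
}
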