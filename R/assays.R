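# Enzyme-assay analytics: molybdenum-blue phosphate calibration, specific
# activity, substrate-inhibition kinetics, activity profiles, inhibition
# panels, and qPCR fold-change analysis.

#' Fit a phosphate calibration line
#'
#' Ordinary least-squares line through molybdenum-blue standards
#' (absorbance at 700 nm vs phosphate concentration).
#'
#' @param standards data.frame (or 2-column matrix) with columns `conc_mM`
#'   and `absorbance`, at least 3 distinct concentrations.
#' @return object of class `calibration_curve`: `slope` (absorbance per mM
#'   Pi), `intercept`, `r_squared`, `n_points`.
#' @export
calibrate <- function(standards) {
  standards <- as.data.frame(standards)
  if (!all(c("conc_mM", "absorbance") %in% names(standards))) {
    names(standards)[1:2] <- c("conc_mM", "absorbance")
  }
  if (nrow(standards) < 3 || length(unique(standards$conc_mM)) < 3) {
    stop("calibration needs >= 3 distinct concentrations", call. = FALSE)
  }
  if (stats::var(standards$conc_mM) == 0) {
    stop("calibration concentrations have zero variance", call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ conc_mM, data = standards)
  s <- suppressWarnings(summary(fit))  # exact standards trip a perfect-fit warning
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 n_points = nrow(standards)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Phosphate calibration: A700 = %.4f * [Pi mM] + %.4f (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Specific activity from a phosphate-release measurement
#'
#' One enzyme unit (U) releases 1 umol inorganic phosphate per minute under
#' the assay conditions. The released phosphate concentration is read off
#' the calibration line from the blank-corrected absorbance, converted to an
#' amount via the reaction volume, then normalized by incubation time and
#' enzyme amount (dilution-corrected).
#'
#' @param a700_sample,a700_blank absorbances at 700 nm.
#' @param curve a [calibrate()] result.
#' @param reaction_volume_uL reaction volume in microlitres.
#' @param incubation_time_min incubation time in minutes.
#' @param enzyme_mg enzyme amount in mg.
#' @param dilution fold-dilution of the enzyme into the assay (multiplies
#'   the result), default 1.
#' @return specific activity in U/mg. Negative computed release clamps to 0
#'   with a warning.
#' @export
specific_activity <- function(a700_sample, a700_blank, curve,
                              reaction_volume_uL, incubation_time_min,
                              enzyme_mg, dilution = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  if (reaction_volume_uL <= 0 || incubation_time_min <= 0 || enzyme_mg <= 0 ||
      dilution <= 0) {
    stop("volume, time, enzyme amount and dilution must be positive", call. = FALSE)
  }
  pi_mM <- (a700_sample - a700_blank - curve$intercept) / curve$slope
  if (pi_mM < 0) {
    warning("computed phosphate release is negative; clamping to 0")
    pi_mM <- 0
  }
  pi_umol <- pi_mM * reaction_volume_uL / 1000  # mM * uL = nmol; /1000 = umol
  pi_umol / incubation_time_min / enzyme_mg * dilution
}

#' Substrate-inhibition rate law
#'
#' `v = Vmax * S / (Km + S * (1 + S / Ki))`. The rate is zero at `S = 0`,
#' rises to a maximum at `S_opt = sqrt(Km * Ki)` where
#' `v = Vmax / (1 + 2 * sqrt(Km / Ki))`, and declines as excess substrate
#' inhibits the enzyme. As `Ki -> Inf` the law reduces to plain
#' Michaelis-Menten.
#'
#' @param S substrate concentration (mM), scalar or vector, nonnegative.
#' @param Vmax maximal rate (U/mg).
#' @param Km Michaelis constant (mM).
#' @param Ki substrate-inhibition constant (mM).
#' @return rate(s) in U/mg.
#' @export
rate_substrate_inhibition <- function(S, Vmax, Km, Ki) {
  if (any(S < 0)) stop("substrate concentration must be nonnegative", call. = FALSE)
  if (Vmax < 0 || Km <= 0 || Ki <= 0) {
    stop("Vmax must be nonnegative; Km and Ki positive", call. = FALSE)
  }
  Vmax * S / (Km + S * (1 + S / Ki))
}

#' Fit the substrate-inhibition model to rate data
#'
#' Nonlinear least squares (Levenberg-Marquardt, bounded multi-start from a
#' fixed start list) of `v = Vmax*S/(Km + S*(1 + S/Ki))`. Standard errors
#' come from the Jacobian at the optimum. If the data show no inhibition
#' signal (monotone non-decreasing rates), a warning is issued and Ki is
#' reported as `Inf` with a plain Michaelis-Menten fit.
#'
#' @param data data.frame with columns `S_mM` and `v` (>= 5 points spanning
#'   both sides of the rate maximum for a full fit).
#' @return object of class `si_fit` with components `Vmax`, `Km`, `Ki`,
#'   `se` (named vector), `rss`, `S_opt` (= sqrt(Km*Ki)), `data`, `fit`
#'   (the underlying nls object). Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals`.
#' @export
fit_substrate_inhibition <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("S_mM", "v") %in% names(data))) names(data)[1:2] <- c("S_mM", "v")
  if (nrow(data) < 5) stop("need >= 5 (S, v) points", call. = FALSE)
  if (any(data$S_mM < 0) || any(data$v < 0)) {
    stop("S and v must be nonnegative", call. = FALSE)
  }
  data <- data[order(data$S_mM), ]
  # inhibition signal: the observed maximum must lie strictly inside the range
  v_smooth <- data$v
  imax <- which.max(v_smooth)
  monotone <- imax >= nrow(data) - 1L && all(diff(v_smooth) >= -1e-12 * max(v_smooth))
  if (monotone) {
    warning("no substrate-inhibition signal (monotone rates); Ki unbounded, fitting plain Michaelis-Menten")
    mm <- minpack.lm::nlsLM(v ~ Vmax * S_mM / (Km + S_mM), data = data,
                            start = list(Vmax = max(data$v) * 1.2,
                                         Km = stats::median(data$S_mM)),
                            lower = c(1e-9, 1e-9),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(mm)
    se <- summary(mm)$coefficients[, "Std. Error"]
    return(structure(list(Vmax = unname(cf["Vmax"]), Km = unname(cf["Km"]),
                          Ki = Inf,
                          se = c(Vmax = unname(se["Vmax"]), Km = unname(se["Km"]),
                                 Ki = NA_real_),
                          rss = sum(stats::residuals(mm)^2),
                          S_opt = Inf, data = data, fit = mm),
                     class = "si_fit"))
  }
  S_at_max <- data$S_mM[imax]
  v_at_max <- data$v[imax]
  # start grid around moment-based guesses (fixed, deterministic)
  starts <- expand.grid(
    Vmax = v_at_max * c(1.5, 2.5, 4),
    Km = S_at_max * c(0.3, 1),
    Ki = S_at_max * c(1, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      v ~ Vmax * S_mM / (Km + S_mM * (1 + S_mM / Ki)), data = data,
      start = as.list(starts[i, ]),
      lower = c(1e-9, 1e-9, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                           ptol = 1e-14))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("substrate-inhibition fit failed from every start", call. = FALSE)
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 3), names(cf)))
  structure(list(Vmax = unname(cf["Vmax"]), Km = unname(cf["Km"]),
                 Ki = unname(cf["Ki"]),
                 se = c(Vmax = unname(se["Vmax"]), Km = unname(se["Km"]),
                        Ki = unname(se["Ki"])),
                 rss = best$rss,
                 S_opt = sqrt(unname(cf["Km"]) * unname(cf["Ki"])),
                 data = data, fit = fit),
            class = "si_fit")
}

#' @export
print.si_fit <- function(x, ...) {
  cat("Substrate-inhibition kinetics fit: v = Vmax*S/(Km + S(1 + S/Ki))\n")
  cat(sprintf("  Vmax = %.4g U/mg (SE %.3g)\n", x$Vmax, x$se["Vmax"]))
  cat(sprintf("  Km   = %.4g mM   (SE %.3g)\n", x$Km, x$se["Km"]))
  if (is.finite(x$Ki)) {
    cat(sprintf("  Ki   = %.4g mM   (SE %.3g)\n", x$Ki, x$se["Ki"]))
    cat(sprintf("  S_opt = sqrt(Km*Ki) = %.4g mM; v(S_opt) = %.4g U/mg\n",
                x$S_opt, rate_substrate_inhibition(x$S_opt, x$Vmax, x$Km, x$Ki)))
  } else {
    cat("  Ki   = Inf (no inhibition signal; plain Michaelis-Menten)\n")
  }
  cat(sprintf("  RSS = %.4g on %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
summary.si_fit <- function(object, ...) {
  tab <- data.frame(estimate = c(object$Vmax, object$Km, object$Ki),
                    std_error = object$se,
                    row.names = c("Vmax", "Km", "Ki"))
  out <- list(coefficients = tab, S_opt = object$S_opt, rss = object$rss,
              n = nrow(object$data))
  class(out) <- "summary.si_fit"
  out
}

#' @export
print.summary.si_fit <- function(x, ...) {
  print(x$coefficients)
  cat(sprintf("S_opt = %.4g mM; RSS = %.4g on %d points\n", x$S_opt, x$rss, x$n))
  invisible(x)
}

#' @export
coef.si_fit <- function(object, ...) {
  c(Vmax = object$Vmax, Km = object$Km, Ki = object$Ki)
}

#' @export
residuals.si_fit <- function(object, ...) {
  object$data$v - predict(object, object$data$S_mM)
}

#' @export
predict.si_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$S_mM
       else if (is.data.frame(newdata)) newdata$S_mM else newdata
  if (is.finite(object$Ki)) {
    rate_substrate_inhibition(S, object$Vmax, object$Km, object$Ki)
  } else {
    object$Vmax * S / (object$Km + S)
  }
}

#' @export
plot.si_fit <- function(x, ...) {
  S <- x$data$S_mM
  grid <- exp(seq(log(max(min(S[S > 0]), 1e-4)), log(max(S)), length.out = 200))
  graphics::plot(S, x$data$v, log = "x", xlab = "[S] (mM)", ylab = "v (U/mg)",
                 main = "Substrate-inhibition kinetics", ...)
  graphics::lines(grid, predict(x, grid), col = "steelblue", lwd = 2)
  if (is.finite(x$S_opt)) graphics::abline(v = x$S_opt, lty = 3)
  invisible(x)
}

#' Locate maxima and plateaus in an activity profile
#'
#' Finds local maxima of a relative-activity profile (e.g. activity vs pH)
#' above a prominence floor; runs of adjacent points that tie with the
#' running maximum within their standard deviations merge into a plateau.
#'
#' @param x ordinate values (pH, temperature, days), strictly increasing.
#' @param relative_activity activity as % of maximum (or of reference).
#' @param sd per-point standard deviations (%, recycled); used to merge
#'   near-ties into plateaus. Default 0.
#' @param prominence_floor minimal % activity a maximum must reach.
#' @return data.frame `x_start`, `x_end`, `activity` — one row per maximum;
#'   `x_start == x_end` for a point maximum, a range for a plateau.
#' @export
profile_maxima <- function(x, relative_activity, sd = 0, prominence_floor = 10) {
  if (length(x) < 4) stop("need >= 4 profile points", call. = FALSE)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  if (length(relative_activity) != length(x)) stop("length mismatch", call. = FALSE)
  sd <- rep_len(sd, length(x))
  y <- relative_activity
  n <- length(y)
  tol <- pmax(sd, 1e-9)
  # group adjacent within-sd ties into candidate plateaus
  grp <- integer(n); grp[1] <- 1L
  for (i in 2:n) {
    grp[i] <- if (abs(y[i] - y[i - 1]) <= max(tol[i], tol[i - 1])) grp[i - 1]
              else grp[i - 1] + 1L
  }
  g_y <- tapply(y, grp, mean)
  g_x1 <- tapply(x, grp, min); g_x2 <- tapply(x, grp, max)
  ng <- length(g_y)
  is_max <- logical(ng)
  for (g in seq_len(ng)) {
    left_ok <- g == 1 || g_y[g] > g_y[g - 1]
    right_ok <- g == ng || g_y[g] > g_y[g + 1]
    is_max[g] <- left_ok && right_ok && g_y[g] >= prominence_floor
  }
  data.frame(x_start = as.numeric(g_x1[is_max]), x_end = as.numeric(g_x2[is_max]),
             activity = as.numeric(g_y[is_max]))
}

#' Activity relative to a reference condition
#'
#' Expresses each activity in a profile as a percentage of the activity at a
#' reference ordinate (e.g. the 4 degree control of a thermostability
#' series, or day 0 of a storage series).
#'
#' @param x ordinate values.
#' @param activity raw activities (same length).
#' @param reference_x ordinate of the reference condition (must be present
#'   in `x`).
#' @return numeric vector of percentages.
#' @export
relative_retention <- function(x, activity, reference_x) {
  i <- match(reference_x, x)
  if (is.na(i)) stop("reference x not found in the series", call. = FALSE)
  if (activity[i] == 0) stop("reference activity is zero", call. = FALSE)
  activity / activity[i] * 100
}

#' Rank additives by inhibition strength
#'
#' Orders an additive panel by ascending relative activity (strongest
#' inhibitor first); entries whose activities tie within `tie_tol` share a
#' rank group.
#'
#' @param panel named numeric: relative activity (%) per additive.
#' @param tie_tol absolute % difference treated as a tie.
#' @return data.frame `additive`, `relative_activity`, `rank` (ties share a
#'   rank), sorted ascending by activity.
#' @export
rank_inhibition <- function(panel, tie_tol = 0) {
  if (length(panel) == 0) stop("empty panel", call. = FALSE)
  ord <- order(panel, names(panel))
  act <- panel[ord]
  rnk <- integer(length(act)); rnk[1] <- 1L
  if (length(act) > 1) for (i in 2:length(act)) {
    rnk[i] <- if (act[i] - act[i - 1] <= tie_tol) rnk[i - 1] else rnk[i - 1] + 1L
  }
  data.frame(additive = names(act), relative_activity = unname(act), rank = rnk,
             stringsAsFactors = FALSE)
}

# robust z-score outlier flag (median/MAD rule)
.mad_outlier <- function(x, z_cut = 3.5) {
  med <- stats::median(x)
  madv <- stats::mad(x)  # normal-consistent constant 1.4826
  if (madv == 0) return(rep(FALSE, length(x)))
  abs(x - med) / madv > z_cut
}

#' Relative expression analysis by the 2^-ddCt method
#'
#' For each condition computes per-replicate dCt = Ct(target) - Ct(reference),
#' ddCt = mean dCt(condition) - mean dCt(control), and fold change
#' 2^-ddCt. Replicate dCt outliers are flagged (and removed before testing)
#' by a median-absolute-deviation rule (robust z > `mad_z`). Significance
#' against the control is reported from both an exact two-sided Mann-Whitney
#' test (exact for group sizes <= `exact_max`, normal approximation above)
#' and a Welch t test.
#'
#' @param data data.frame with columns `condition`, `replicate`, `ct_target`,
#'   `ct_reference`; >= 3 replicates per condition.
#' @param control name of the control condition.
#' @param mad_z robust z cutoff for outlier flagging (default 3.5).
#' @param exact_max largest per-group n for which the Mann-Whitney test is
#'   exact (default 8).
#' @return object of class `expression_result`: data.frame with one row per
#'   non-control condition (`condition`, `n`, `n_outliers`, `delta_ct_mean`,
#'   `delta_ct_sd`, `ddct`, `fold_change`, `p_mann_whitney`, `p_welch_t`)
#'   plus attributes `control` and `control_delta_ct`.
#' @export
expression_analysis <- function(data, control, mad_z = 3.5, exact_max = 8) {
  data <- as.data.frame(data)
  need <- c("condition", "ct_target", "ct_reference")
  if (!all(need %in% names(data))) {
    stop("data needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!control %in% data$condition) {
    stop("control condition not present: ", control, call. = FALSE)
  }
  if (any(!is.finite(data$ct_target)) || any(!is.finite(data$ct_reference))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  data$delta_ct <- data$ct_target - data$ct_reference
  conds <- unique(data$condition)
  counts <- table(data$condition)
  if (any(counts < 3)) {
    stop("every condition needs >= 3 replicates", call. = FALSE)
  }
  clean <- function(cond) {
    d <- data$delta_ct[data$condition == cond]
    out <- .mad_outlier(d, mad_z)
    list(kept = d[!out], n_out = sum(out))
  }
  ctrl <- clean(control)
  rows <- lapply(setdiff(conds, control), function(cond) {
    cc <- clean(cond)
    ddct <- mean(cc$kept) - mean(ctrl$kept)
    exact <- length(cc$kept) <= exact_max && length(ctrl$kept) <= exact_max
    p_mw <- suppressWarnings(stats::wilcox.test(cc$kept, ctrl$kept,
                                                exact = exact))$p.value
    p_t <- tryCatch(stats::t.test(cc$kept, ctrl$kept)$p.value,
                    error = function(e) NA_real_)
    data.frame(condition = cond, n = length(cc$kept), n_outliers = cc$n_out,
               delta_ct_mean = mean(cc$kept), delta_ct_sd = stats::sd(cc$kept),
               ddct = ddct, fold_change = 2^(-ddct),
               p_mann_whitney = p_mw, p_welch_t = p_t,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, control = control,
            control_delta_ct = c(mean = mean(ctrl$kept), sd = stats::sd(ctrl$kept),
                                 n = length(ctrl$kept)),
            class = c("expression_result", "data.frame"))
}

#' @export
print.expression_result <- function(x, ...) {
  ctrl <- attr(x, "control_delta_ct")
  cat(sprintf("Relative expression vs control %s (dCt %.3f +/- %.3f, n = %d)\n",
              sQuote(attr(x, "control")), ctrl["mean"], ctrl["sd"], ctrl["n"]))
  cat("Outliers flagged by MAD rule (robust z > 3.5) and removed before testing.\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
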