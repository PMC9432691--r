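# Assay analytics: calibration, specific activity, substrate-inhibition
# kinetics, activity profiles, inhibition ranking, qPCR fold changes.

test_that("calibration fits the standards line and rejects degenerate input", {
  std <- data.frame(conc_mM = c(0, 0.25, 0.5, 1), absorbance = c(0, 0.5, 1, 2))
  cal <- calibrate(std)
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_error(calibrate(std[1:2, ]), ">= 3")
  expect_error(calibrate(data.frame(conc_mM = rep(0.5, 4),
                                    absorbance = c(1, 1.1, 0.9, 1))), ">= 3")
})

test_that("calibration recovers a generator slope within 1% at 1% noise", {
  set.seed(71)
  conc <- c(0, 0.2, 0.4, 0.8, 1.2, 1.6)
  truth_slope <- 1.8; truth_int <- 0.03
  abs_vals <- truth_int + truth_slope * conc +
    stats::rnorm(6, 0, 0.01 * truth_slope * mean(conc))
  cal <- calibrate(data.frame(conc_mM = conc, absorbance = abs_vals))
  expect_equal(cal$slope, truth_slope, tolerance = 0.01)
})

test_that("specific activity realises the unit definition and round-trips", {
  cal <- calibrate(data.frame(conc_mM = c(0, 0.5, 1), absorbance = c(0, 1, 2)))
  expect_equal(suppressWarnings(specific_activity(0.4, 0.4, cal, 50, 15, 1e-3)), 0)
  # construct a measurement releasing exactly 1 umol/min/mg:
  # 1 umol in 50 uL = 20 mM; 15 min, 0.0667 mg scaled -> use 1 min, 1 mg
  a700 <- 20 * cal$slope  # blank 0, intercept 0
  expect_equal(specific_activity(a700, 0, cal, 50, 1, 1), 1)
  # generator round-trip at arbitrary parameters
  truth_u <- 37.5; vol <- 80; tmin <- 12; mg <- 2.5e-4
  pi_umol <- truth_u * tmin * mg
  pi_mM <- pi_umol * 1000 / vol
  a <- cal$intercept + cal$slope * pi_mM + 0.05
  expect_equal(specific_activity(a, 0.05, cal, vol, tmin, mg), truth_u,
               tolerance = 1e-9)
  expect_warning(specific_activity(0.1, 0.3, cal, 50, 15, 1e-3), "negative")
})

test_that("substrate-inhibition rate law has the right shape and limits", {
  Vmax <- 228; Km <- 0.65; Ki <- 2.23
  expect_equal(rate_substrate_inhibition(0, Vmax, Km, Ki), 0)
  s_opt <- sqrt(Km * Ki)
  expect_equal(s_opt, 1.2039, tolerance = 1e-4)
  v_opt <- rate_substrate_inhibition(s_opt, Vmax, Km, Ki)
  expect_equal(v_opt, Vmax / (1 + 2 * sqrt(Km / Ki)), tolerance = 1e-12)
  expect_equal(v_opt, 109.6, tolerance = 1e-3)
  # numeric grid maximum agrees with the closed form
  grid <- seq(0.01, 10, by = 0.001)
  v <- rate_substrate_inhibition(grid, Vmax, Km, Ki)
  expect_equal(grid[which.max(v)], s_opt, tolerance = 1e-3)
  # strictly up before the optimum, strictly down after
  expect_true(all(diff(v[grid < s_opt]) > 0))
  expect_true(all(diff(v[grid > s_opt]) < 0))
  # Ki -> Inf limit is plain Michaelis-Menten
  S <- c(0.1, 0.65, 2, 3.75)
  expect_equal(rate_substrate_inhibition(S, Vmax, Km, 1e12),
               Vmax * S / (Km + S), tolerance = 1e-9)
  expect_error(rate_substrate_inhibition(-1, Vmax, Km, Ki), "nonnegative")
})

test_that("kinetics fit is the identity on noise-free generated data", {
  g <- gen_kinetics_table(noise_sd = 0)
  fit <- fit_substrate_inhibition(g$data)
  expect_equal(fit$Vmax, 228, tolerance = 1e-6)
  expect_equal(fit$Km, 0.65, tolerance = 1e-6)
  expect_equal(fit$Ki, 2.23, tolerance = 1e-6)
  expect_equal(fit$S_opt, sqrt(0.65 * 2.23), tolerance = 1e-6)
  expect_equal(unname(coef(fit)), c(fit$Vmax, fit$Km, fit$Ki))
  expect_equal(predict(fit, g$data$S_mM), g$data$v, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("kinetics fit flags monotone data and degrades to Michaelis-Menten", {
  S <- c(0.05, 0.1, 0.3, 0.8, 2, 3.75)
  v <- 100 * S / (0.4 + S)
  expect_warning(fit <- fit_substrate_inhibition(data.frame(S_mM = S, v = v)),
                 "no substrate-inhibition")
  expect_equal(fit$Ki, Inf)
  expect_equal(fit$Vmax, 100, tolerance = 1e-4)
  expect_equal(fit$Km, 0.4, tolerance = 1e-4)
  expect_error(fit_substrate_inhibition(data.frame(S_mM = 1:3, v = 1:3)), ">= 5")
})

test_that("profile maxima finds the three pH optima with a mid plateau", {
  # emulating a broad tri-modal pH profile: peaks at 3, a 4.5-5 plateau, and 6
  ph <- c(2, 2.5, 3, 3.5, 4, 4.5, 5, 5.5, 6, 6.5, 7, 8, 8.5)
  act <- c(40, 55, 78, 60, 65, 88, 87, 70, 100, 72, 55, 30, 20)
  sdv <- c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3)
  mx <- profile_maxima(ph, act, sd = sdv, prominence_floor = 20)
  expect_equal(nrow(mx), 3L)
  expect_equal(mx$x_start[1], 3)
  expect_equal(mx$x_end[1], 3)
  expect_equal(c(mx$x_start[2], mx$x_end[2]), c(4.5, 5))  # plateau
  expect_equal(mx$x_start[3], 6)
  # monotone series: single endpoint maximum
  mono <- profile_maxima(1:6, c(10, 20, 35, 50, 70, 90))
  expect_equal(nrow(mono), 1L)
  expect_equal(mono$x_start, 6)
  # flat series: one plateau spanning the range
  flat <- profile_maxima(1:5, rep(50, 5), sd = 1)
  expect_equal(nrow(flat), 1L)
  expect_equal(c(flat$x_start, flat$x_end), c(1, 5))
})

test_that("relative retention reproduces planted thermostability values", {
  temps <- c(4, 37, 50, 60, 70)
  act <- c(120, 118, 48, 0, 0)  # planted: 40% of control at 50, abolished at 60
  rel <- relative_retention(temps, act, reference_x = 4)
  expect_equal(rel[1], 100)
  expect_equal(rel[3], 40, tolerance = 1e-12)
  expect_equal(rel[4], 0)
  expect_equal(relative_retention(1:4, rep(7, 4), 1), rep(100, 4))
  expect_error(relative_retention(temps, c(0, 1, 1, 1, 1), 4), "zero")
  expect_error(relative_retention(temps, act, 99), "not found")
})

test_that("inhibition ranking orders the additive panel, strongest first", {
  panel <- c(nil = 100, Ca = 114, Zn = 93, K = 88, Mg = 80, InsS6 = 72,
             Co = 60, Mn = 50, Cu = 45, Fe = 29)
  r <- rank_inhibition(panel)
  expect_equal(r$additive[1:8], c("Fe", "Cu", "Mn", "Co", "InsS6", "Mg", "K", "Zn"))
  expect_true(all(diff(r$relative_activity) >= 0))
  # tie grouping
  r2 <- rank_inhibition(c(a = 50, b = 50, c = 80), tie_tol = 0)
  expect_equal(r2$rank, c(1L, 1L, 2L))
  expect_equal(rank_inhibition(c(only = 42))$additive, "only")
  # random panel against the sort oracle
  set.seed(12)
  p <- stats::setNames(stats::runif(8, 0, 120), letters[1:8])
  expect_equal(rank_inhibition(p)$additive, names(sort(p)))
  expect_error(rank_inhibition(numeric()), "empty")
})

test_that("a +1 cycle dCt shift gives exactly fold 0.5; identical groups give fold 1", {
  d <- data.frame(
    condition = rep(c("ctrl", "cond"), each = 4),
    replicate = rep(1:4, 2),
    ct_target = c(20.0, 20.3, 19.8, 20.1, 21.0, 21.3, 20.8, 21.1),  # +1 exactly
    ct_reference = rep(c(16.0, 16.3, 15.8, 16.1), 2))
  res <- expression_analysis(d, control = "ctrl")
  expect_equal(res$ddct, 1)
  expect_equal(res$fold_change, 0.5)
  same <- data.frame(condition = rep(c("ctrl", "cond"), each = 3),
                     replicate = rep(1:3, 2),
                     ct_target = rep(c(20, 20.5, 19.5), 2),
                     ct_reference = rep(16, 6))
  res2 <- suppressWarnings(expression_analysis(same, control = "ctrl"))
  expect_equal(res2$fold_change, 1)
  expect_equal(res2$p_mann_whitney, 1)
  expect_error(expression_analysis(d, control = "nope"), "control")
})

test_that("exact Mann-Whitney p-values match full permutation enumeration", {
  set.seed(33)
  for (rep in 1:6) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- stats::rnorm(n1); y <- stats::rnorm(n2, mean = rep %% 3)
    p_pkg <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(p_pkg, oracle_mann_whitney_p(x, y), tolerance = 1e-12)
  }
})

test_that("MAD outlier rule flags gross dCt outliers before testing", {
  d <- data.frame(
    condition = rep(c("ctrl", "cond"), each = 6),
    replicate = rep(1:6, 2),
    ct_target = c(20.0, 20.1, 19.9, 20.05, 19.95, 28.0,  # one wild replicate
                  21.0, 21.1, 20.9, 21.05, 20.95, 21.02),
    ct_reference = rep(16, 12))
  res <- expression_analysis(d, control = "ctrl")
  ctrl <- attr(res, "control_delta_ct")
  expect_equal(unname(ctrl["n"]), 5)  # outlier dropped
  expect_equal(res$n_outliers, 0L)
  expect_equal(res$ddct, 1, tolerance = 0.05)
})
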