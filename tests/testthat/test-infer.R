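# Specificity inference: class candidates, exclusion by absence, attack
# ranking, kinase-evidence disambiguation, preference fitting, call assembly.

test_that("class candidates resolve to the 1 or 2 member states", {
  pair <- candidates_for_class("D/L-Ins(1,2,3,4,5)P5")
  expect_length(pair, 2L)
  expect_setequal(lapply(pair, `[[`, "positions"),
                  list(c(1L, 2L, 3L, 4L, 5L), c(1L, 2L, 3L, 5L, 6L)))
  meso <- candidates_for_class("Ins(1,2,3,4,6)P5")
  expect_length(meso, 1L)
  expect_equal(meso[[1]]$positions, c(1L, 2L, 3L, 4L, 6L))
  expect_equal(candidates_for_class("Ins(1,3,4,5,6)P5")[[1]]$positions,
               c(1L, 3L, 4L, 5L, 6L))
  expect_error(candidates_for_class("Ins(1,2,9)P3"), "out of range")
})

test_that("absence of the missing-2 product class excludes position 2", {
  g <- gen_peak_table(seed = 3, noise = "none", noise_sd = 0)
  expect_equal(exclude_by_absence(g$peaks, phospho_state(1:6)), 2L)
  # with every class present nothing is excluded
  g2 <- gen_peak_table(seed = 3, weights = stats::setNames(rep(1, 6), 1:6),
                       forbidden_locants = integer(), noise = "none")
  expect_equal(exclude_by_absence(g2$peaks, phospho_state(1:6)), integer())
  expect_error(exclude_by_absence(data.frame(), phospho_state(1:6)), "non-empty")
})

test_that("exclusion recovers any mirror-closed forbidden set from generated tables", {
  for (forb in list(2L, 5L, c(1L, 3L), c(4L, 6L), c(2L, 5L))) {
    w <- stats::setNames(rep(1, 6), 1:6)
    w[as.character(forb)] <- 0
    g <- gen_peak_table(seed = 11, weights = w, forbidden_locants = forb,
                        noise = "none")
    expect_equal(exclude_by_absence(g$peaks, phospho_state(1:6)), sort(forb))
  }
})

test_that("attack ranking normalizes first-generation shares onto locant sets", {
  peaks <- data.frame(
    time_h = 0.5,
    class = c("D/L-Ins(1,2,3,4,5)P5", "D/L-Ins(1,2,4,5,6)P5", "Ins(1,2,3,4,6)P5"),
    area = c(50, 25, 25))
  r <- rank_initial_attack(peaks, phospho_state(1:6))
  expect_equal(r$share, c(0.5, 0.25, 0.25))
  expect_equal(r$locants[[1]], c(4L, 6L))
  expect_setequal(r$locants[2:3], list(c(1L, 3L), 5L))
  expect_equal(sum(r$share), 1)
  # permutation equivariance: relabeling input rows changes nothing
  r2 <- rank_initial_attack(peaks[c(3, 1, 2), ], phospho_state(1:6))
  expect_equal(r2, r, ignore_attr = TRUE)
  # generated paper-like pattern puts the 4/6 pair on top
  g <- gen_peak_table(seed = 5, noise = "none")
  r3 <- rank_initial_attack(g$peaks, phospho_state(1:6))
  expect_equal(r3$locants[[1]], c(4L, 6L))
  expect_error(rank_initial_attack(
    data.frame(time_h = 1, class = "D/L-Ins(1,2,3,4,5)P5", area = 0),
    phospho_state(1:6)), "nonzero")
})

test_that("ranking shares recover generator weights at the first timepoint", {
  # early shares approximate w_p / sum(w) (pairs: summed over the two locants)
  g <- gen_peak_table(seed = 9, noise = "none",
                      timepoints = c(0.05, 2, 4, 8))  # early sampling
  r <- rank_initial_attack(g$peaks, phospho_state(1:6))
  truth <- g$truth$weights
  truth_share <- function(loc) sum(truth[as.character(loc)]) / sum(truth)
  for (i in seq_len(nrow(r))) {
    expect_equal(r$share[i], truth_share(r$locants[[i]]), tolerance = 0.05)
  }
})

test_that("kinase evidence resolves the 6-OH/4-OH pair without excluding the mirror", {
  cand <- candidates_for_class("D/L-Ins(1,2,3,4,5)P5")
  res <- enantio_disambiguate(cand, itpk1_evidence(conversion = 0.12))
  expect_equal(res$status, "resolved_D")
  expect_equal(res$resolved[[1]]$positions, 1:5)
  expect_match(res$note, "NOT excluded")
  # below detection: ambiguous, nothing confirmed
  res0 <- enantio_disambiguate(cand, itpk1_evidence(conversion = 0))
  expect_equal(res0$status, "ambiguous")
  expect_length(res0$resolved, 0L)
  # meso candidate needs no kinase evidence
  resm <- enantio_disambiguate(candidates_for_class("Ins(1,2,3,4,6)P5"),
                               itpk1_evidence())
  expect_equal(resm$status, "resolved_D")
  # uninformative evidence errors
  both <- kinase_evidence(accepted_substrates = list("D-Ins(1,2,3,4,5)P5",
                                                     "D-Ins(1,2,3,5,6)P5"),
                          rejected_substrates = list("D-Ins(1,3,4,5,6)P5"),
                          observed_conversion_fraction = 0.5)
  expect_error(enantio_disambiguate(cand, both), "uninformative")
  expect_error(kinase_evidence(list("D-Ins(1,2,3,4,5)P5"),
                               list("D-Ins(1,2,3,4,5)P5"), 0.5), "overlap")
})

test_that("preference fit recovers truth weights exactly from noise-free tables", {
  g <- gen_peak_table(seed = 1, noise = "none", noise_sd = 0)
  net <- build_network(phospho_state(1:6), 2)
  fit <- fit_preferences(g$peaks, net, resolve_locant = 6)
  truth_norm <- g$truth$weights / sum(g$truth$weights)
  expect_equal(unname(fit$weights), unname(truth_norm), tolerance = 1e-4)
  expect_true(fit$mirror_degenerate)
  expect_lt(fit$rss, 1e-10)
})

test_that("preference fit recovers a single-path system's weight exactly", {
  chain <- build_network(phospho_state(6), integer())
  k1 <- 0.45
  tc <- simulate_network(chain, rate_model(c(`6` = k1)), initial = 1,
                         times = c(0, 1, 2, 4))
  ct <- class_timecourse(tc)
  peaks <- data.frame(time_h = ct$time_h, class = ct$class, area = ct$abundance)
  fit <- suppressWarnings(fit_preferences(peaks, chain))
  expect_equal(unname(fit$raw_weights["6"]), k1, tolerance = 1e-4)
})

test_that("preference fit recovers weights within 20% under 5% noise (median of seeds)", {
  net <- build_network(phospho_state(1:6), 2)
  truth_norm <- default_truth_weights() / sum(default_truth_weights())
  free <- c("1", "3", "4", "5", "6")
  errs <- vapply(1:11, function(s) {
    g <- gen_peak_table(seed = s, noise_sd = 0.05)
    fit <- fit_preferences(g$peaks, net, resolve_locant = 6)
    max(abs(fit$weights[free] / truth_norm[free] - 1))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.20)
})

test_that("preference fit rejects unusable tables", {
  net <- build_network(phospho_state(1:6), 2)
  zero <- data.frame(time_h = c(1, 2), class = "D/L-Ins(1,2,3,4,5)P5",
                     area = c(0, 0))
  expect_error(fit_preferences(zero, net), "nonzero")
  one_t <- data.frame(time_h = 1, class = "D/L-Ins(1,2,3,4,5)P5", area = 3)
  expect_error(fit_preferences(one_t, net), "timepoints")
})

test_that("specificity call assembles the published pattern from paper-like inputs", {
  g <- gen_peak_table(seed = 2, noise = "none")
  call_obj <- run_call_chain(g$peaks)
  expect_equal(call_obj$excluded_locants, 2L)
  expect_equal(call_obj$ranked_attacks$label[1], "D6")
  expect_equal(call_obj$enantiomer_status, "resolved_D")
  expect_true(any(grepl("cannot be discounted", call_obj$notes)))
  # uniform attack, nothing excluded: ambiguous call
  g2 <- gen_peak_table(seed = 2, weights = stats::setNames(rep(1, 6), 1:6),
                       forbidden_locants = integer(), noise = "none")
  excl2 <- exclude_by_absence(g2$peaks, phospho_state(1:6))
  rank2 <- rank_initial_attack(g2$peaks, phospho_state(1:6))
  call2 <- make_call(excl2, rank2, NULL)
  expect_equal(call2$excluded_locants, integer())
  expect_equal(call2$enantiomer_status, "ambiguous")
  # contradictory inputs rejected
  fake_rank <- rank2
  expect_error(make_call(5L, fake_rank, NULL), "inconsistent")
})

test_that("specificity call serializes to JSON", {
  g <- gen_peak_table(seed = 4, noise = "none")
  call_obj <- run_call_chain(g$peaks)
  js <- jsonlite::fromJSON(specificity_call_json(call_obj))
  expect_equal(js$excluded_locants, 2L)
  expect_equal(js$enantiomer_status, "resolved_D")
})
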