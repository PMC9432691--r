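# Degradation network construction and kinetic simulation.

test_that("network from InsP6 sparing position 2 has 32 nodes, 80 edges, terminal Ins2P", {
  net <- build_network(phospho_state(1:6), forbidden_locants = 2)
  expect_length(net$nodes, 32L)
  expect_equal(nrow(net$edges), 80L)
  expect_equal(terminal_nodes(net), "2")
  # every node retains the 2-phosphate; every edge removes exactly one locant
  expect_true(all(vapply(net$node_positions, function(p) 2L %in% p, logical(1))))
  for (i in seq_len(nrow(net$edges))) {
    parent <- net$node_positions[[net$edges$parent[i]]]
    child <- net$node_positions[[net$edges$child[i]]]
    expect_equal(sort(c(child, net$edges$removed[i])), parent)
  }
})

test_that("degenerate networks: no constraints gives the full lattice, blocked start is inert", {
  full <- build_network(phospho_state(1:6))
  expect_length(full$nodes, 64L)
  expect_equal(terminal_nodes(full), "Ins")
  inert <- build_network(phospho_state(2), forbidden_locants = 2)
  expect_length(inert$nodes, 1L)
  expect_equal(nrow(inert$edges), 0L)
})

test_that("simulation conserves phosphate and is monotone in substrate and Pi", {
  net <- build_network(phospho_state(1:6), 2)
  rm <- rate_model(c(`1` = 0.1, `3` = 0.1, `4` = 0.2, `5` = 0.2, `6` = 0.6))
  tc <- simulate_network(net, rm, initial = 5, times = c(0, 0.5, 2, 4, 8))
  tot <- total_phosphate(tc)
  expect_equal(tot, rep(30, 5), tolerance = 1e-6)
  expect_true(all(diff(tc$conc[, "123456"]) <= 1e-9))
  expect_true(all(diff(tc$pi) >= -1e-9))
  expect_true(all(tc$conc >= -1e-8))
  # shared-enzyme Michaelis-Menten law conserves too
  rm2 <- rate_model(c(`1` = 0.1, `3` = 0.1, `4` = 0.2, `5` = 0.2, `6` = 0.6),
                    kinetic_law = "shared_enzyme_mm",
                    Vmax = 3, Km = 0.65, Ki = 2.23)
  tc2 <- simulate_network(net, rm2, initial = 5, times = c(0, 0.5, 2, 4, 8))
  expect_equal(total_phosphate(tc2), rep(30, 5), tolerance = 1e-6)
  expect_true(all(diff(tc2$conc[, "123456"]) <= 1e-9))
})

test_that("zero weights freeze the system", {
  net <- build_network(phospho_state(1:6), 2)
  rm <- rate_model(stats::setNames(numeric(6), as.character(1:6)))
  tc <- simulate_network(net, rm, initial = 5, times = c(0, 1, 2))
  expect_equal(unname(tc$conc[, "123456"]), rep(5, 3))
  expect_equal(tc$pi, rep(0, 3))
})

test_that("first-order decay of the start species matches its exact exponential", {
  net <- build_network(phospho_state(c(4, 5, 6)), forbidden_locants = integer())
  w <- c(`4` = 0.3, `5` = 0.7, `6` = 1.1)
  rm <- rate_model(w)
  times <- c(0, 0.4, 1, 2.5, 6)
  tc <- simulate_network(net, rm, initial = 2, times = times)
  k_out <- sum(w)  # total outflow of the start node
  expect_equal(unname(tc$conc[, "456"]), 2 * exp(-k_out * times), tolerance = 1e-6)
  # single-step chain against the sequential-decay closed form
  chain <- build_network(phospho_state(6), forbidden_locants = integer())
  k1 <- 0.9
  tc2 <- simulate_network(chain, rate_model(c(`6` = k1)), initial = 1.5,
                          times = times)
  oracle <- oracle_bateman(k = k1, a0 = 1.5, times = times)
  expect_equal(unname(tc2$conc[, "6"]), oracle[, 1], tolerance = 1e-6)
  expect_equal(unname(tc2$conc[, "Ins"]), oracle[, 2], tolerance = 1e-6)
})

test_that("branched two-step system matches its analytic solution", {
  # nodes 25, 2, 5, Ins; fluxes 25->5 (remove 2), 25->2 (remove 5), then ->Ins
  net <- build_network(phospho_state(c(2, 5)), forbidden_locants = integer())
  w <- c(`2` = 0.8, `5` = 0.25)
  rm <- rate_model(w)
  times <- c(0, 0.3, 1, 3)
  tc <- simulate_network(net, rm, initial = 1, times = times)
  k_tot <- sum(w)
  a_25 <- exp(-k_tot * times)
  # species "5" (lost the 2-phosphate): fed at w2*[25], drained at w5
  b5 <- w[["2"]] / (k_tot - w[["5"]]) * (exp(-w[["5"]] * times) - exp(-k_tot * times))
  b2 <- w[["5"]] / (k_tot - w[["2"]]) * (exp(-w[["2"]] * times) - exp(-k_tot * times))
  expect_equal(unname(tc$conc[, "25"]), a_25, tolerance = 1e-6)
  expect_equal(unname(tc$conc[, "5"]), b5, tolerance = 1e-6)
  expect_equal(unname(tc$conc[, "2"]), b2, tolerance = 1e-6)
  expect_equal(unname(tc$conc[, "Ins"]), 1 - a_25 - b5 - b2, tolerance = 1e-6)
})

test_that("dominant 6-attack makes D/L-Ins(1,2,3,4,5)P5 the most abundant early InsP5 class", {
  net <- build_network(phospho_state(1:6), 2)
  rm <- rate_model(c(`1` = 0.05, `3` = 0.05, `4` = 0.1, `5` = 0.1, `6` = 0.8))
  tc <- simulate_network(net, rm, initial = 5, times = c(0, 0.5))
  ct <- class_timecourse(tc)
  p5 <- ct[grepl("P5$", ct$class) & ct$time_h == 0.5, ]
  expect_equal(p5$class[which.max(p5$abundance)], "D/L-Ins(1,2,3,4,5)P5")
})

test_that("class time course sums pair members and preserves phosphate accounting", {
  net <- build_network(phospho_state(1:6), 2)
  rm <- rate_model(c(`1` = 0.1, `3` = 0.2, `4` = 0.2, `5` = 0.1, `6` = 0.5))
  tc <- simulate_network(net, rm, initial = 4, times = c(0, 1, 4))
  ct <- class_timecourse(tc)
  # pair summation: the 4/6-removal products form one class
  direct <- tc$conc[, "12345"] + tc$conc[, "12356"]
  got <- ct$abundance[ct$class == "D/L-Ins(1,2,3,4,5)P5"]
  expect_equal(got, unname(direct))
  # class-level conservation: sum over classes of n_p * abundance + Pi constant
  np_of <- function(cls) if (cls %in% c("Pi", "solvent_front")) 0L
    else length(parse_name(cls)$positions)
  ct$np <- vapply(ct$class, np_of, integer(1))
  tot <- as.numeric(tapply(ct$abundance * ct$np, ct$time_h, sum)) +
    as.numeric(tapply(ct$abundance[ct$class == "Pi"],
                      ct$time_h[ct$class == "Pi"], sum))
  expect_equal(tot, rep(24, 3), tolerance = 1e-6)
})

test_that("route ranking orders edges by share with correct normalization", {
  net <- build_network(phospho_state(1:6), 2)
  rm <- rate_model(c(`1` = 1, `3` = 1, `4` = 2, `5` = 2, `6` = 4))
  rr <- route_ranking(rm, net, node = "123456")
  expect_equal(rr$removed[1], 6L)
  expect_equal(rr$share[1], 0.4)
  expect_equal(sum(rr$share), 1)
  uniform <- route_ranking(rate_model(stats::setNames(rep(1, 6), 1:6)
                                      [as.character(c(1, 3, 4, 5, 6))]),
                           net, node = "123456")
  expect_equal(uniform$share, rep(0.2, 5))
  all_nodes <- route_ranking(rm, net)
  shares_by_node <- tapply(all_nodes$share, all_nodes$node, sum)
  expect_true(all(abs(shares_by_node - 1) < 1e-12))
})

test_that("validation rejects bad simulation inputs", {
  net <- build_network(phospho_state(1:6), 2)
  rm <- rate_model(c(`6` = 1))
  expect_error(simulate_network(net, rm, initial = -1, times = c(0, 1)),
               "nonnegative")
  expect_error(simulate_network(net, rm, initial = 1, times = c(1, 0.5)),
               "increasing")
  expect_error(simulate_network(net, rm, initial = c(`Ins(1,3)P2` = 1),
                                times = c(0, 1)),
               "not in network")
})

test_that("network export writes edge lists and DOT text", {
  net <- build_network(phospho_state(c(4, 6)), integer())
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".dot")
  write_network(net, f1)
  expect_equal(nrow(utils::read.table(f1, header = TRUE, sep = "\t")), nrow(net$edges))
  write_network(net, f2, format = "dot")
  expect_match(readLines(f2)[1], "digraph")
})
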