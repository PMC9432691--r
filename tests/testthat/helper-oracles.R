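# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation it checks.

# mirror oracle: apply the C2/C5 reflection as an explicit position map
oracle_mirror <- function(positions) {
  map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 6L, `5` = 5L, `6` = 4L)
  sort(unname(map[as.character(positions)]))
}

# all 64 locant subsets as a list of integer vectors
all_subsets <- function() {
  out <- list(integer())
  for (n in 1:6) out <- c(out, utils::combn(6L, n, simplify = FALSE))
  out
}

# closed-form sequential decay (Bateman) for a linear chain
# A1 -> A2 -> ... -> An with distinct rate constants k (length n-1),
# starting from A1 = a0; returns matrix times x species
oracle_bateman <- function(k, a0, times) {
  n <- length(k) + 1L
  conc <- matrix(0, nrow = length(times), ncol = n)
  conc[, 1] <- a0 * exp(-k[1] * times)
  for (j in 2:n) {
    kk <- k[seq_len(j - 1)]     # rates along the chain into species j
    lam <- c(k, 0)[seq_len(j)]  # decay constant of species i (terminal: 0)
    coefs <- vapply(seq_len(j), function(i) {
      prod(kk) / prod(lam[-i] - lam[i])
    }, numeric(1))
    conc[, j] <- a0 * vapply(times, function(t) sum(coefs * exp(-lam * t)),
                             numeric(1))
  }
  conc
}

# regex-route motif matcher: independent of the package's window scanner
oracle_motif_starts <- function(seq, motif_expr) {
  rx <- gsub("x", "[A-Z]", motif_expr, fixed = TRUE)
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (same tail convention as stats::wilcox.test in the no-ties exact case)
oracle_mann_whitney_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx_sets <- utils::combn(n1 + n2, n1, simplify = FALSE)
  all_r <- rank(c(x, y))
  w_perm <- vapply(idx_sets, function(ix) sum(all_r[ix]) - n1 * (n1 + 1) / 2,
                   numeric(1))
  mu <- n1 * n2 / 2
  p <- if (w_obs > mu) mean(w_perm >= w_obs) else mean(w_perm <= w_obs)
  min(2 * p, 1)
}

# text-route PDB distance oracle: parses fixed-width coordinate records
# directly and measures all pairwise distances
oracle_pocket <- function(pdb_lines, cutoff = 5.0) {
  is_coord <- grepl("^(ATOM|HETATM)", pdb_lines)
  rec <- pdb_lines[is_coord]
  parse_num <- function(s) as.numeric(trimws(s))
  atoms <- data.frame(
    type = trimws(substr(rec, 1, 6)),
    name = trimws(substr(rec, 13, 16)),
    resno = as.integer(trimws(substr(rec, 23, 26))),
    x = parse_num(substr(rec, 31, 38)),
    y = parse_num(substr(rec, 39, 46)),
    z = parse_num(substr(rec, 47, 54)),
    element = trimws(substr(rec, 77, 78)),
    stringsAsFactors = FALSE)
  p_atoms <- atoms[atoms$type == "HETATM" & atoms$element == "P", ]
  prot <- atoms[atoms$type == "ATOM", ]
  out <- list()
  for (i in seq_len(nrow(p_atoms))) {
    d <- sqrt((prot$x - p_atoms$x[i])^2 + (prot$y - p_atoms$y[i])^2 +
                (prot$z - p_atoms$z[i])^2)
    keep <- d <= cutoff
    if (!any(keep)) next
    out[[i]] <- data.frame(resno = prot$resno[keep], dist = d[keep])
  }
  do.call(rbind, out)
}

# convenience: run the full specificity call chain on one peak table
run_call_chain <- function(peaks, conversion = 0.12, threshold = 0.05) {
  parent <- phospho_state(1:6)
  excl <- exclude_by_absence(peaks, parent)
  ranking <- rank_initial_attack(peaks, parent)
  enantio <- NULL
  if (length(ranking$locants[[1]]) == 2) {
    cand <- candidates_for_class(ranking$class[1])
    enantio <- enantio_disambiguate(cand, itpk1_evidence(conversion, threshold))
  }
  make_call(excl, ranking, enantio, parent = parent)
}
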