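# Dephosphorylation reaction networks.
#
# A phytase removes one phosphate per catalytic event, so the species
# reachable from a starting inositol phosphate form a directed acyclic
# graph on the subset lattice of ring locants: an edge joins a parent
# pattern to the child obtained by deleting one (non-forbidden) locant.
# Simulation integrates mass-action kinetics over this graph and books one
# liberated inorganic phosphate per removal event.

.state_key <- function(positions) {
  if (length(positions) == 0) "Ins" else paste(sort(positions), collapse = "")
}

.key_positions <- function(key) {
  if (key == "Ins") integer() else as.integer(strsplit(key, "")[[1]])
}

#' Build a dephosphorylation network
#'
#' Enumerates every species reachable from `start` by repeated removal of a
#' single non-forbidden phosphate, with one edge per removal. Node and edge
#' ordering is deterministic (by phosphate count descending, then
#' lexicographic locant order).
#'
#' @param start a [phospho_state] (or locant vector); the starting substrate,
#'   typically InsP6 = `phospho_state(1:6)`.
#' @param forbidden_locants integer vector of locants the enzyme never
#'   attacks (e.g. `2` for an enzyme sparing the axial 2-phosphate).
#' @return object of class `degradation_network`: list with `nodes`
#'   (character keys, e.g. `"123456"`), `node_positions` (named list of
#'   integer vectors), `edges` (data.frame `parent`, `child`, `removed`),
#'   `forbidden`, `start`.
#' @examples
#' net <- build_network(phospho_state(1:6), forbidden_locants = 2)
#' length(net$nodes)   # 32
#' nrow(net$edges)     # 80
#' @export
build_network <- function(start, forbidden_locants = integer()) {
  start <- .assert_state(start)
  start <- convert_numbering(start, "D")
  if (length(forbidden_locants)) {
    forbidden_locants <- as.integer(forbidden_locants)
    if (any(forbidden_locants < 1L | forbidden_locants > 6L)) {
      stop("forbidden locants must lie in 1..6", call. = FALSE)
    }
    forbidden_locants <- sort(unique(forbidden_locants))
  }
  seen <- new.env(parent = emptyenv())
  edges_p <- character(); edges_c <- character(); edges_r <- integer()
  queue <- list(start$positions)
  assign(.state_key(start$positions), start$positions, envir = seen)
  while (length(queue)) {
    pos <- queue[[1]]; queue <- queue[-1]
    removable <- setdiff(pos, forbidden_locants)
    for (p in removable) {
      child <- setdiff(pos, p)
      ck <- .state_key(child)
      edges_p <- c(edges_p, .state_key(pos))
      edges_c <- c(edges_c, ck)
      edges_r <- c(edges_r, p)
      if (!exists(ck, envir = seen, inherits = FALSE)) {
        assign(ck, child, envir = seen)
        queue <- c(queue, list(child))
      }
    }
  }
  keys <- ls(seen)
  node_positions <- lapply(keys, .key_positions)
  names(node_positions) <- keys
  # order: phosphate count descending, then lexicographic
  np <- vapply(node_positions, length, integer(1))
  ord <- order(-np, keys)
  keys <- keys[ord]; node_positions <- node_positions[ord]
  edges <- data.frame(parent = edges_p, child = edges_c, removed = edges_r,
                      stringsAsFactors = FALSE)
  edges <- edges[order(-nchar(edges$parent), edges$parent, edges$removed), ]
  rownames(edges) <- NULL
  structure(list(nodes = keys, node_positions = node_positions, edges = edges,
                 forbidden = forbidden_locants, start = start),
            class = "degradation_network")
}

#' @export
print.degradation_network <- function(x, ...) {
  cat("Dephosphorylation network from", format_name(x$start, prefix = "none"), "\n")
  cat("  forbidden locants:",
      if (length(x$forbidden)) paste(x$forbidden, collapse = ", ") else "none", "\n")
  cat("  ", length(x$nodes), "species, ", nrow(x$edges), "removal edges\n")
  term <- terminal_nodes(x)
  cat("  terminal species:", paste(term, collapse = ", "), "\n")
  invisible(x)
}

#' Terminal species of a network
#'
#' Nodes with no removable phosphate (every remaining locant forbidden, or
#' none left).
#' @param network a [build_network] result.
#' @return character vector of node keys.
#' @export
terminal_nodes <- function(network) {
  network$nodes[!network$nodes %in% network$edges$parent]
}

#' Rate model for a dephosphorylation network
#'
#' Every removal edge gets rate constant `k = position_weights[removed] *
#' level_scale[n_phosphates(parent)]`. Under `"first_order"` kinetics each
#' edge consumes its parent at `k * [parent]` (units 1/h). Under
#' `"shared_enzyme_mm"` all substrate species compete for one enzyme pool
#' with substrate inhibition: edge flux `k * Vmax * [parent] /
#' (Km + T * (1 + T / Ki))`, `T` the summed concentration of species that
#' still have removable phosphates.
#'
#' @param position_weights named nonnegative numeric, names `"1"`..`"6"`;
#'   relative propensity of attack at each ring position.
#' @param level_scale named nonnegative numeric, names `"1"`..`"6"` =
#'   phosphate count of the parent; multiplier expressing, e.g., that InsP5s
#'   are better substrates than InsP6 (preset: `level_scale_insp5_boost()`).
#' @param kinetic_law `"first_order"` or `"shared_enzyme_mm"`.
#' @param Vmax,Km,Ki enzyme parameters for `"shared_enzyme_mm"` (enzyme
#'   concentration absorbed into `Vmax`); `Km`, `Ki` in mM.
#' @return object of class `rate_model`.
#' @export
rate_model <- function(position_weights,
                       level_scale = NULL,
                       kinetic_law = c("first_order", "shared_enzyme_mm"),
                       Vmax = NULL, Km = NULL, Ki = NULL) {
  kinetic_law <- match.arg(kinetic_law)
  w <- position_weights
  if (is.null(names(w))) names(w) <- as.character(seq_along(w))
  if (any(w < 0) || anyNA(w)) stop("position weights must be nonnegative", call. = FALSE)
  full_w <- stats::setNames(numeric(6), as.character(1:6))
  full_w[names(w)] <- w
  ls_full <- stats::setNames(rep(1, 6), as.character(1:6))
  if (!is.null(level_scale)) {
    if (is.null(names(level_scale))) names(level_scale) <- as.character(seq_along(level_scale))
    if (any(level_scale < 0)) stop("level_scale must be nonnegative", call. = FALSE)
    ls_full[names(level_scale)] <- level_scale
  }
  if (kinetic_law == "shared_enzyme_mm") {
    if (is.null(Vmax) || is.null(Km) || is.null(Ki)) {
      stop("shared_enzyme_mm requires Vmax, Km and Ki", call. = FALSE)
    }
    if (Km <= 0 || Ki <= 0 || Vmax < 0) {
      stop("Km and Ki must be positive, Vmax nonnegative", call. = FALSE)
    }
  }
  structure(list(position_weights = full_w, level_scale = ls_full,
                 kinetic_law = kinetic_law,
                 enzyme_params = if (kinetic_law == "shared_enzyme_mm")
                   list(Vmax = Vmax, Km = Km, Ki = Ki) else NULL),
            class = "rate_model")
}

#' Level-scale preset making InsP5 species better substrates than InsP6
#' @param boost multiplier applied at the InsP5 level (default 2).
#' @return named numeric usable as `level_scale` in [rate_model()].
#' @export
level_scale_insp5_boost <- function(boost = 2) {
  stats::setNames(c(1, 1, 1, 1, boost, 1), as.character(1:6))
}

.edge_rate_constants <- function(network, rates) {
  np_parent <- nchar(network$edges$parent)
  np_parent[network$edges$parent == "Ins"] <- 0L
  rates$position_weights[as.character(network$edges$removed)] *
    rates$level_scale[as.character(np_parent)]
}

#' Simulate sequential dephosphorylation
#'
#' Integrates the network kinetics (stiff solver, relative tolerance 1e-8)
#' from the given initial concentrations, reporting species concentrations
#' and cumulative liberated inorganic phosphate at the requested times. One
#' Pi equivalent is booked per removal event, so total ring-bound plus free
#' phosphate is conserved.
#'
#' @param network a [build_network] result.
#' @param rates a [rate_model].
#' @param initial named numeric of starting concentrations (mM); names are
#'   node keys (`"123456"`) or parseable species names (`"Ins(1,2,3,4,5,6)P6"`).
#'   A single unnamed number is placed on the network's start species.
#' @param times numeric vector of report times (hours), strictly increasing,
#'   starting at 0.
#' @param pi0 initial inorganic phosphate (mM), default 0.
#' @return object of class `timecourse`: list with `times`, `conc`
#'   (matrix time x species, mM) and `pi` (mM).
#' @export
simulate_network <- function(network, rates, initial, times, pi0 = 0) {
  stopifnot(inherits(network, "degradation_network"), inherits(rates, "rate_model"))
  if (length(times) < 2 || any(diff(times) <= 0) || times[1] < 0) {
    stop("times must be strictly increasing and start at >= 0", call. = FALSE)
  }
  if (any(initial < 0) || pi0 < 0) stop("concentrations must be nonnegative", call. = FALSE)
  nodes <- network$nodes
  y0 <- stats::setNames(numeric(length(nodes)), nodes)
  if (is.null(names(initial))) {
    if (length(initial) != 1) {
      stop("unnamed initial must be a single value for the start species", call. = FALSE)
    }
    y0[.state_key(network$start$positions)] <- initial
  } else {
    for (nm in names(initial)) {
      key <- if (nm %in% nodes) nm else .state_key(parse_name(nm)$positions)
      if (!key %in% nodes) stop("initial species not in network: ", nm, call. = FALSE)
      y0[key] <- initial[[nm]]
    }
  }
  k <- .edge_rate_constants(network, rates)
  pidx <- match(network$edges$parent, nodes)
  cidx <- match(network$edges$child, nodes)
  nonterminal <- nodes %in% network$edges$parent
  law <- rates$kinetic_law
  ep <- rates$enzyme_params
  nsp <- length(nodes)
  deriv <- function(t, y, parms) {
    conc <- pmax(y[seq_len(nsp)], 0)
    flux <- if (law == "first_order") {
      k * conc[pidx]
    } else {
      Tt <- sum(conc[nonterminal])
      k * ep$Vmax * conc[pidx] / (ep$Km + Tt * (1 + Tt / ep$Ki))
    }
    dy <- numeric(nsp + 1L)
    for (e in seq_along(flux)) {
      dy[pidx[e]] <- dy[pidx[e]] - flux[e]
      dy[cidx[e]] <- dy[cidx[e]] + flux[e]
    }
    dy[nsp + 1L] <- sum(flux)
    list(dy)
  }
  t_solver <- if (times[1] == 0) times else c(0, times)
  sol <- deSolve::ode(y = c(y0, Pi = pi0), times = t_solver, func = deriv,
                      parms = NULL, method = "lsoda", rtol = 1e-8, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("integration failed on [%g, %g] h", t_solver[1], max(times)),
         call. = FALSE)
  }
  sol <- sol[match(times, sol[, "time"]), , drop = FALSE]
  conc <- sol[, nodes, drop = FALSE]
  conc[conc < 0 & conc > -1e-10] <- 0
  rownames(conc) <- NULL
  structure(list(times = times, conc = conc, pi = unname(sol[, "Pi"]),
                 network = network),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat("Dephosphorylation time course:", length(x$times), "timepoints,",
      ncol(x$conc), "species\n")
  cat("  t =", paste(x$times, collapse = ", "), "h\n")
  cat("  Pi:", paste(signif(x$pi, 4), collapse = ", "), "mM\n")
  invisible(x)
}

#' Total ring-bound plus free phosphate at each time (conservation check)
#' @param tc a [simulate_network] result.
#' @return numeric vector, one total per timepoint (mM phosphate).
#' @export
total_phosphate <- function(tc) {
  np <- vapply(colnames(tc$conc),
               function(key) length(.key_positions(key)), integer(1))
  as.numeric(tc$conc %*% np) + tc$pi
}

# Exact propagator for the linear (first-order) system: builds the rate
# matrix A (species x species) and returns concentrations at the requested
# times via eigendecomposition, falling back to Matrix::expm when the
# spectrum is ill-conditioned (near-defective A). Used by fitting code where
# thousands of forward solves are needed; simulate_network() remains the
# general entry point.
.propagate_first_order <- function(network, k, y0, times) {
  nodes <- network$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  pidx <- match(network$edges$parent, nodes)
  cidx <- match(network$edges$child, nodes)
  for (e in seq_along(k)) {
    A[pidx[e], pidx[e]] <- A[pidx[e], pidx[e]] - k[e]
    A[cidx[e], pidx[e]] <- A[cidx[e], pidx[e]] + k[e]
  }
  conc <- try({
    eg <- eigen(A)
    if (any(abs(Im(eg$values)) > 1e-9)) stop("complex spectrum")
    V <- Re(eg$vectors); lam <- Re(eg$values)
    if (kappa(V, exact = FALSE) >= 1e10) stop("near-defective")
    a0 <- solve(V, y0)
    vapply(times, function(t) as.numeric(V %*% (exp(lam * t) * a0)), numeric(n))
  }, silent = TRUE)
  if (inherits(conc, "try-error")) conc <- NULL
  if (is.null(conc)) {
    conc <- vapply(times, function(t) {
      as.numeric(Matrix::expm(Matrix::Matrix(A * t)) %*% y0)
    }, numeric(n))
  }
  conc[conc < 0] <- 0
  dimnames(conc) <- list(nodes, NULL)
  t(conc)  # times x species
}

#' Collapse a time course onto achiral co-elution classes
#'
#' Sums species abundances over the members of each enantiomer co-elution
#' class, i.e. the view an achiral HPLC column gives. With
#' `merge_insp1 = TRUE` all monophosphates are added to the inorganic
#' phosphate series (`"solvent_front"`), mimicking columns on which InsP1
#' co-elutes with Pi at the solvent front.
#'
#' @param tc a [simulate_network] result.
#' @param merge_insp1 merge InsP1 species into the Pi / solvent-front series.
#' @return data.frame `time_h`, `class`, `abundance` (tidy; one row per class
#'   per timepoint), classes ordered by phosphate count then name. The Pi
#'   series appears as class `"Pi"` (or `"solvent_front"` when merging).
#' @export
class_timecourse <- function(tc, merge_insp1 = FALSE) {
  stopifnot(inherits(tc, "timecourse"))
  keys <- colnames(tc$conc)
  if (length(keys) == 0) {
    return(data.frame(time_h = numeric(), class = character(),
                      abundance = numeric(), stringsAsFactors = FALSE))
  }
  pos_list <- lapply(keys, .key_positions)
  np <- vapply(pos_list, length, integer(1))
  cls <- vapply(pos_list, function(p) canonical_class(phospho_state(p))$display_name,
                character(1))
  pi_series <- tc$pi
  keep <- rep(TRUE, length(keys))
  pi_label <- "Pi"
  if (merge_insp1) {
    m1 <- np == 1L
    if (any(m1)) pi_series <- pi_series + rowSums(tc$conc[, m1, drop = FALSE])
    keep <- !m1
    pi_label <- "solvent_front"
  }
  out <- list()
  ucls <- unique(data.frame(cls = cls[keep], np = np[keep], stringsAsFactors = FALSE))
  ucls <- ucls[order(ucls$np, ucls$cls), ]
  for (i in seq_len(nrow(ucls))) {
    cols <- keep & cls == ucls$cls[i]
    out[[length(out) + 1L]] <- data.frame(
      time_h = tc$times, class = ucls$cls[i],
      abundance = rowSums(tc$conc[, cols, drop = FALSE]),
      stringsAsFactors = FALSE)
  }
  out[[length(out) + 1L]] <- data.frame(time_h = tc$times, class = pi_label,
                                        abundance = pi_series,
                                        stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank removal routes by relative flux share
#'
#' For each (or one) network node, orders the outgoing removal edges by rate
#' constant and reports each edge's share of the node's total outflow
#' (shares sum to 1 per node). This quantifies the "major vs minor route"
#' picture of a degradation scheme.
#'
#' @param rates a [rate_model].
#' @param network a [build_network] result.
#' @param node optional node key (e.g. `"123456"`); default: all non-terminal
#'   nodes.
#' @return data.frame `node`, `removed`, `child`, `rate_constant`, `share`,
#'   sorted within node by descending share.
#' @export
route_ranking <- function(rates, network, node = NULL) {
  stopifnot(inherits(network, "degradation_network"), inherits(rates, "rate_model"))
  edges <- network$edges
  edges$rate_constant <- .edge_rate_constants(network, rates)
  if (!is.null(node)) {
    edges <- edges[edges$parent == node, ]
    if (nrow(edges) == 0) stop("node has no outgoing edges: ", node, call. = FALSE)
  }
  parts <- split(edges, edges$parent)
  parts <- lapply(parts, function(d) {
    tot <- sum(d$rate_constant)
    d$share <- if (tot > 0) d$rate_constant / tot else rep(NA_real_, nrow(d))
    d[order(-d$share, d$removed), ]
  })
  res <- do.call(rbind, parts)
  res <- data.frame(node = res$parent, removed = res$removed, child = res$child,
                    rate_constant = res$rate_constant, share = res$share,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Export a network as an edge list or DOT text
#' @param network a [build_network] result.
#' @param path output file.
#' @param format `"edgelist"` (tab-separated parent/child/removed) or `"dot"`.
#' @return invisibly, the path.
#' @export
write_network <- function(network, path, format = c("edgelist", "dot")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- c("digraph degradation {",
               sprintf('  "%s" -> "%s" [label="-%d"];',
                       network$edges$parent, network$edges$child,
                       network$edges$removed),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}
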