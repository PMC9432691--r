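# Positional-specificity inference from achiral HPLC product profiles.
#
# An achiral anion-exchange column reports co-elution classes, not
# individual enantiomers: removal of the 4- or the 6-phosphate from InsP6
# gives the same peak (the D/L-Ins(1,2,3,4,5)P5 pair), as does removal of 1
# or 3. Inference therefore proceeds in three steps: exclusion of positions
# whose product class never appears, ranking of initial attack positions by
# first-generation peak shares, and resolution of the 4/6 (or 1/3)
# ambiguity with evidence from a kinase of known enantiospecificity.

#' Member states of a co-elution class
#'
#' @param class_id display name of a class from [coelution_partition()]
#'   (e.g. `"D/L-Ins(1,2,3,4,5)P5"`).
#' @param n_phosphates phosphate count of the class; default inferred from
#'   the name.
#' @return list of 1 (meso) or 2 (enantiomer pair) [phospho_state] objects.
#' @export
candidates_for_class <- function(class_id, n_phosphates = NULL) {
  st <- parse_name(class_id)
  n <- length(st$positions)
  if (!is.null(n_phosphates) && n_phosphates != n) {
    stop("class name has ", n, " locants but n_phosphates = ", n_phosphates,
         call. = FALSE)
  }
  classes <- coelution_partition(n)
  hit <- Filter(function(cl) cl$display_name == class_id, classes)
  if (length(hit) == 0) {
    # accept a member name in place of the class display name
    cl <- canonical_class(st)
    hit <- Filter(function(x) x$display_name == cl$display_name, classes)
    if (length(hit) == 0) stop("unknown co-elution class: ", class_id, call. = FALSE)
  }
  cl <- hit[[1]]
  if (cl$chirality == "meso") list(cl$representative)
  else list(cl$representative, cl$partner)
}

#' Validate a peak table
#'
#' A peak table holds observed (or simulated) HPLC peak areas: columns
#' `time_h`, `class` (a co-elution class display name, `"Pi"` or
#' `"solvent_front"`), `area` (nonnegative).
#'
#' @param peaks data.frame.
#' @return the table, invisibly, after checks.
#' @export
validate_peak_table <- function(peaks) {
  if (!is.data.frame(peaks) || nrow(peaks) == 0) {
    stop("peak table must be a non-empty data.frame", call. = FALSE)
  }
  need <- c("time_h", "class", "area")
  if (!all(need %in% names(peaks))) {
    stop("peak table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(peaks$area < 0)) stop("peak areas must be nonnegative", call. = FALSE)
  invisible(peaks)
}

# first-generation product classes of a parent: one class per removable
# locant, possibly shared by two locants (enantiomer pair)
.first_gen_classes <- function(parent) {
  parent <- .assert_state(parent)
  res <- list()
  for (p in parent$positions) {
    child <- phospho_state(setdiff(parent$positions, p))
    nm <- canonical_class(child)$display_name
    res[[nm]] <- sort(c(res[[nm]], p))
  }
  res  # named list: class display name -> locant(s) whose removal yields it
}

#' Exclude attack positions by product absence
#'
#' A ring position is called excluded when the co-elution class of the
#' product of its removal stays below an absence floor at every timepoint.
#' The floor is a fraction of the summed first-generation-level area at each
#' timepoint (default 1%). Because enantiomer pairs share a peak, a position
#' in a chiral pair can only be excluded together with its mirror partner.
#'
#' @param peaks a peak table (see [validate_peak_table()]).
#' @param parent the substrate [phospho_state] (e.g. InsP6).
#' @param floor_frac absence floor as a fraction of total first-generation
#'   area per timepoint.
#' @return sorted integer vector of excluded locants.
#' @export
exclude_by_absence <- function(peaks, parent, floor_frac = 0.01) {
  validate_peak_table(peaks)
  parent <- .assert_state(parent)
  fg <- .first_gen_classes(parent)
  times <- sort(unique(peaks$time_h))
  times <- times[times > 0]
  if (length(times) == 0) stop("peak table has no post-zero timepoints", call. = FALSE)
  area_of <- function(cls, t) {
    a <- peaks$area[peaks$class == cls & peaks$time_h == t]
    if (length(a) == 0) 0 else sum(a)
  }
  excluded <- integer()
  for (cls in names(fg)) {
    absent <- TRUE
    for (t in times) {
      tot <- sum(vapply(names(fg), area_of, numeric(1), t = t))
      if (tot == 0) next
      if (area_of(cls, t) >= floor_frac * tot) { absent <- FALSE; break }
    }
    if (absent) excluded <- c(excluded, fg[[cls]])
  }
  sort(unique(excluded))
}

#' Rank initial attack positions from first-generation peak shares
#'
#' At the earliest timepoint with nonzero first-generation product signal,
#' maps each observed product class back to the attack locant(s) that
#' produce it and reports normalized area shares. Classes arising from an
#' enantiomer pair map to an unresolved locant pair (e.g. `{4,6}`).
#'
#' @inheritParams exclude_by_absence
#' @return data.frame `locants` (list-column of integer vectors), `class`,
#'   `share`, sorted by descending share; shares sum to 1.
#' @export
rank_initial_attack <- function(peaks, parent) {
  validate_peak_table(peaks)
  parent <- .assert_state(parent)
  fg <- .first_gen_classes(parent)
  times <- sort(unique(peaks$time_h))
  t_use <- NA_real_
  for (t in times) {
    tot <- sum(peaks$area[peaks$time_h == t & peaks$class %in% names(fg)])
    if (tot > 0) { t_use <- t; break }
  }
  if (is.na(t_use)) {
    stop("no nonzero first-generation product areas in the table", call. = FALSE)
  }
  areas <- vapply(names(fg), function(cls) {
    sum(peaks$area[peaks$time_h == t_use & peaks$class == cls])
  }, numeric(1))
  observed <- areas > 0  # absent classes are the exclusion step's business
  shares <- areas[observed] / sum(areas[observed])
  res <- data.frame(class = names(fg)[observed], share = unname(shares),
                    stringsAsFactors = FALSE)
  res$locants <- unname(fg[observed])
  res <- res[order(-res$share, res$class), c("locants", "class", "share")]
  rownames(res) <- NULL
  attr(res, "timepoint") <- t_use
  res
}

#' Kinase evidence for enantiomer discrimination
#'
#' Describes an assay with a kinase of known substrate enantiospecificity
#' (e.g. a kinase that pyrophosphorylates InsP6 and D-Ins(1,2,3,4,5)P5 but
#' not D-Ins(1,2,3,5,6)P5): which states it accepts/rejects, the observed
#' conversion fraction of the unknown fraction, and the detection threshold.
#'
#' @param accepted_substrates,rejected_substrates lists of [phospho_state]
#'   (or parseable names), D numbering; must be disjoint.
#' @param observed_conversion_fraction fraction of the unknown converted (0..1).
#' @param detection_threshold conversion fraction counted as a positive (0..1).
#' @return object of class `kinase_evidence`.
#' @export
kinase_evidence <- function(accepted_substrates, rejected_substrates,
                            observed_conversion_fraction,
                            detection_threshold = 0.05) {
  norm <- function(x) lapply(x, function(s) {
    if (is.character(s)) s <- parse_name(s)
    convert_numbering(.assert_state(s), "D")
  })
  acc <- norm(accepted_substrates)
  rej <- norm(rejected_substrates)
  keyify <- function(l) vapply(l, function(s) .state_key(s$positions), character(1))
  if (length(intersect(keyify(acc), keyify(rej)))) {
    stop("accepted and rejected substrate sets overlap", call. = FALSE)
  }
  if (observed_conversion_fraction < 0 || observed_conversion_fraction > 1) {
    stop("conversion fraction must lie in [0, 1]", call. = FALSE)
  }
  if (detection_threshold <= 0 || detection_threshold >= 1) {
    stop("detection threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(accepted = acc, rejected = rej,
                 conversion = observed_conversion_fraction,
                 threshold = detection_threshold),
            class = "kinase_evidence")
}

#' Resolve an enantiomer pair with kinase evidence
#'
#' Given the 1-2 candidate states behind a co-elution peak and evidence from
#' a stereospecific kinase, decides which enantiomer is demonstrably present.
#' A positive conversion at or above threshold with exactly one accepted
#' candidate confirms that candidate as PRESENT; the mirror partner is NOT
#' thereby excluded (a mixture cannot be ruled out) and the note records
#' this asymmetry. Below threshold, the accepted candidate is
#' absent-or-below-detection. A meso singleton is resolved trivially.
#'
#' @param candidates list of 1 or 2 [phospho_state] (a mirror pair), as from
#'   [candidates_for_class()].
#' @param ev a [kinase_evidence].
#' @return list with `status` (`"resolved_D"`, `"resolved_L"` or
#'   `"ambiguous"`), `resolved` (list of confirmed-present states, possibly
#'   empty), `note`.
#' @export
enantio_disambiguate <- function(candidates, ev) {
  candidates <- lapply(candidates, function(s) convert_numbering(.assert_state(s), "D"))
  if (length(candidates) == 1) {
    if (!is_meso(candidates[[1]])) {
      stop("single candidate must be a meso state", call. = FALSE)
    }
    return(list(status = "resolved_D", resolved = candidates,
                note = "meso compound: no enantiomer ambiguity to resolve"))
  }
  if (length(candidates) != 2) {
    stop("candidates must be a singleton or a mirror pair", call. = FALSE)
  }
  if (!(mirror(candidates[[1]]) == candidates[[2]])) {
    stop("the two candidates are not mirror images", call. = FALSE)
  }
  stopifnot(inherits(ev, "kinase_evidence"))
  keys <- vapply(candidates, function(s) .state_key(s$positions), character(1))
  acc_keys <- vapply(ev$accepted, function(s) .state_key(s$positions), character(1))
  rej_keys <- vapply(ev$rejected, function(s) .state_key(s$positions), character(1))
  in_acc <- keys %in% acc_keys
  in_rej <- keys %in% rej_keys
  if (sum(in_acc) != 1 || !in_rej[!in_acc]) {
    stop(paste("uninformative evidence: the kinase must accept exactly one",
               "candidate and reject the other"), call. = FALSE)
  }
  idx <- which(in_acc)
  # the D-representative is the lexicographically smaller member
  cmp <- .lex_cmp(candidates[[1]]$positions, candidates[[2]]$positions)
  rep_idx <- if (cmp <= 0) 1L else 2L
  if (ev$conversion >= ev$threshold) {
    status <- if (idx == rep_idx) "resolved_D" else "resolved_L"
    partner_name <- format_name(candidates[[if (idx == 1) 2 else 1]], prefix = "D")
    list(status = status, resolved = candidates[idx],
         note = sprintf(paste("conversion %.3f >= threshold %.3f: %s confirmed",
                              "present; the mirror partner %s is NOT excluded",
                              "(a mixture cannot be discounted)"),
                        ev$conversion, ev$threshold,
                        format_name(candidates[[idx]], prefix = "D"), partner_name))
  } else {
    list(status = "ambiguous", resolved = list(),
         note = sprintf(paste("conversion %.3f below threshold %.3f: %s",
                              "absent or below detection; identity unresolved"),
                        ev$conversion, ev$threshold,
                        format_name(candidates[[idx]], prefix = "D")))
  }
}

#' Fit position preferences to an observed peak table
#'
#' Least-squares recovery of the per-position attack weights of a
#' [rate_model] from class-level peak areas. Because HPLC response factors
#' are unknown, both observed and simulated class abundances are normalized
#' per timepoint before comparison; first-order kinetics make the result
#' independent of the (unknown) initial substrate amount. Optimization is
#' bounded multi-start (log-scale, fixed start list) nonlinear least squares
#' over an exact linear-system propagator.
#'
#' Achiral class data determine the weights only up to the ring's mirror
#' symmetry: applying the 1<->3, 4<->6 relabeling to every species and
#' weight leaves all co-elution class abundances identical, so `w` and its
#' mirror fit equally well. The returned orientation is fixed by convention
#' (weight at 6 >= weight at 4; ties broken by weight at 1 <= weight at 3)
#' unless `resolve_locant` pins the dominant member of the 4/6 pair — pass
#' the locant established by kinase evidence.
#'
#' @param peaks a peak table with at least 2 post-zero timepoints.
#' @param network a [build_network] result; its forbidden locants define
#'   which weights are free.
#' @param n_starts number of deterministic multi-starts (default 8).
#' @param resolve_locant optional locant (4 or 6, or 1 or 3) that external
#'   evidence identifies as the dominant attack position of its mirror pair;
#'   orients the returned weights accordingly.
#' @return object of class `preference_fit`: list with `rate_model`
#'   (weights normalized to sum 1 over free locants), `weights`, `rss`,
#'   `convergence`, `n_obs`, `mirror_degenerate` (TRUE when the mirror
#'   orientation is a convention, i.e. the fitted weights are asymmetric).
#' @export
fit_preferences <- function(peaks, network, n_starts = 8,
                            resolve_locant = NULL) {
  validate_peak_table(peaks)
  stopifnot(inherits(network, "degradation_network"))
  times <- sort(unique(peaks$time_h))
  times <- times[times > 0]
  if (length(times) < 2) stop("need at least 2 post-zero timepoints", call. = FALSE)
  free <- sort(setdiff(network$start$positions, network$forbidden))
  # observed classes that the network can produce
  net_classes <- unique(vapply(network$node_positions, function(p) {
    canonical_class(phospho_state(p))$display_name
  }, character(1)))
  obs_cls <- intersect(unique(peaks$class), net_classes)
  if (length(obs_cls) == 0 || all(peaks$area[peaks$class %in% obs_cls] == 0)) {
    stop("no usable (nonzero) class areas in the peak table", call. = FALSE)
  }
  if (length(obs_cls) < length(free)) {
    warning("fewer observed classes (", length(obs_cls), ") than free weights (",
            length(free), "); fit may be non-identifiable")
  }
  obs <- matrix(0, nrow = length(times), ncol = length(obs_cls),
                dimnames = list(NULL, obs_cls))
  for (i in seq_along(times)) for (j in seq_along(obs_cls)) {
    a <- peaks$area[peaks$time_h == times[i] & peaks$class == obs_cls[j]]
    obs[i, j] <- if (length(a)) sum(a) else 0
  }
  row_tot <- rowSums(obs)
  keep_t <- row_tot > 0
  obs_n <- obs[keep_t, , drop = FALSE] / row_tot[keep_t]
  # map each species onto its observed class column (once)
  nodes <- network$nodes
  node_cls <- vapply(network$node_positions, function(p) {
    canonical_class(phospho_state(p))$display_name
  }, character(1))
  cls_col <- match(node_cls, obs_cls)  # NA = class not observed
  y0 <- stats::setNames(numeric(length(nodes)), nodes)
  y0[.state_key(network$start$positions)] <- 1
  edge_removed <- as.character(network$edges$removed)
  predict_shares <- function(logw) {
    w <- stats::setNames(numeric(6), as.character(1:6))
    w[as.character(free)] <- exp(logw)
    k <- unname(w[edge_removed])
    conc <- .propagate_first_order(network, k, y0, times)
    pred <- matrix(0, nrow = length(times), ncol = length(obs_cls))
    for (j in which(!is.na(cls_col))) {
      pred[, cls_col[j]] <- pred[, cls_col[j]] + conc[, j]
    }
    tot <- rowSums(pred)
    pos <- keep_t & tot > 0
    pred[pos, ] <- pred[pos, , drop = FALSE] / tot[pos]
    pred[keep_t, , drop = FALSE]
  }
  objective <- function(logw) {
    p <- try(predict_shares(logw), silent = TRUE)
    if (inherits(p, "try-error")) return(1e6)
    sum((p - obs_n)^2)
  }
  # deterministic start grid: uniform weights at several overall rate scales,
  # plus mild per-position perturbations from a fixed lattice
  base_scales <- c(0.05, 0.2, 0.5, 1, 2, 5, 10, 0.02)[seq_len(n_starts)]
  starts <- lapply(seq_along(base_scales), function(i) {
    jitter <- ((seq_along(free) * 7 + i * 3) %% 5 - 2) * 0.15
    log(base_scales[i]) + jitter
  })
  best <- NULL
  for (st in starts) {
    fit <- try(stats::nlminb(st, objective, control = list(iter.max = 400)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("preference fit failed from every start", call. = FALSE)
  # polish the best solution
  best <- stats::nlminb(best$par, objective,
                        control = list(iter.max = 1000, rel.tol = 1e-12))
  w_hat <- stats::setNames(numeric(6), as.character(1:6))
  w_hat[as.character(free)] <- exp(best$par)
  # orient the mirror-degenerate solution (only meaningful when the network
  # itself is mirror-symmetric, i.e. the forbidden set is mirror-closed)
  symmetric_net <- setequal(network$forbidden, .MIRROR_PERM[network$forbidden])
  w_mirror <- w_hat[as.character(.MIRROR_PERM)]
  names(w_mirror) <- as.character(1:6)
  degenerate <- symmetric_net &&
    !isTRUE(all.equal(unname(w_hat), unname(w_mirror)))
  pick_mirror <- FALSE
  if (!is.null(resolve_locant) && symmetric_net) {
    rl <- as.character(resolve_locant)
    ml <- as.character(.MIRROR_PERM[as.integer(resolve_locant)])
    pick_mirror <- w_mirror[rl] > w_hat[rl] ||
      (w_mirror[rl] == w_hat[rl] && w_hat[ml] > w_hat[rl])
  } else if (degenerate) {
    pick_mirror <- w_mirror["6"] > w_hat["6"] ||
      (w_mirror["6"] == w_hat["6"] && w_mirror["1"] < w_hat["1"])
  }
  if (pick_mirror) w_hat <- w_mirror
  w_norm <- w_hat
  w_norm[as.character(free)] <- w_hat[as.character(free)] / sum(w_hat[as.character(free)])
  structure(list(rate_model = rate_model(w_hat),
                 weights = w_norm, raw_weights = w_hat,
                 rss = best$objective, convergence = best$convergence,
                 n_obs = sum(keep_t) * length(obs_cls),
                 mirror_degenerate = degenerate),
            class = "preference_fit")
}

#' @export
print.preference_fit <- function(x, ...) {
  cat("Position-preference fit (weights normalized over free locants)\n")
  print(round(x$weights, 4))
  cat("residual sum of squares:", format(x$rss, digits = 4),
      "on", x$n_obs, "normalized observations\n")
  invisible(x)
}

#' Assemble a positional-specificity call
#'
#' Combines exclusion, attack-ranking and enantiomer-resolution evidence
#' into a single call: which positions the enzyme does not attack, the
#' ranked attack positions with the top chiral pair resolved where the
#' kinase evidence allows, and explanatory notes.
#'
#' @param excluded integer vector from [exclude_by_absence()].
#' @param ranking data.frame from [rank_initial_attack()].
#' @param enantio result of [enantio_disambiguate()] for the top-ranked
#'   chiral class, or `NULL` if unavailable.
#' @param parent the substrate state (default InsP6).
#' @return object of class `specificity_call`: list with `excluded_locants`,
#'   `ranked_attacks` (data.frame `label`, `locants`, `share`),
#'   `enantiomer_status`, `notes`.
#' @export
make_call <- function(excluded, ranking, enantio = NULL,
                      parent = phospho_state(1:6)) {
  ranked_locants <- sort(unique(unlist(ranking$locants)))
  clash <- intersect(excluded, ranked_locants)
  if (length(clash)) {
    stop("inconsistent inputs: locant(s) ", paste(clash, collapse = ", "),
         " both excluded and ranked as attacked", call. = FALSE)
  }
  notes <- character()
  status <- "ambiguous"
  resolved_key <- NULL
  if (!is.null(enantio)) {
    status <- enantio$status
    notes <- c(notes, enantio$note)
    if (length(enantio$resolved)) {
      resolved_key <- .state_key(enantio$resolved[[1]]$positions)
    }
  }
  parent <- .assert_state(parent)
  labels <- character(nrow(ranking))
  for (i in seq_len(nrow(ranking))) {
    loc <- ranking$locants[[i]]
    if (length(loc) == 1) {
      labels[i] <- paste0("D", loc)
    } else if (!is.null(resolved_key)) {
      # which removal yields the resolved product?
      prod_keys <- vapply(loc, function(p) {
        .state_key(setdiff(parent$positions, p))
      }, character(1))
      hit <- loc[prod_keys == resolved_key]
      if (length(hit) == 1 && ranking$share[i] == max(ranking$share)) {
        other <- setdiff(loc, hit)
        labels[i] <- paste0("D", hit)
        notes <- c(notes, sprintf(
          "top attack pair {%s} resolved to D%d; D%d attack cannot be discounted",
          paste(loc, collapse = ","), hit, other))
      } else {
        labels[i] <- paste0("D", paste(loc, collapse = "/D"))
      }
    } else {
      labels[i] <- paste0("D", paste(loc, collapse = "/D"))
    }
  }
  ranked <- data.frame(label = labels, share = ranking$share,
                       stringsAsFactors = FALSE)
  ranked$locants <- ranking$locants
  if (length(excluded) == 0 && length(notes) == 0) {
    notes <- "no exclusions; attack profile uniform or uninformative"
  }
  structure(list(excluded_locants = excluded,
                 ranked_attacks = ranked[, c("label", "locants", "share")],
                 enantiomer_status = status,
                 notes = notes),
            class = "specificity_call")
}

#' @export
print.specificity_call <- function(x, ...) {
  cat("Positional-specificity call\n")
  cat("  excluded positions:",
      if (length(x$excluded_locants)) paste(x$excluded_locants, collapse = ", ")
      else "none", "\n")
  cat("  ranked initial attacks:\n")
  for (i in seq_len(nrow(x$ranked_attacks))) {
    cat(sprintf("    %-8s share %.3f\n", x$ranked_attacks$label[i],
                x$ranked_attacks$share[i]))
  }
  cat("  enantiomer status:", x$enantiomer_status, "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Serialize a specificity call to JSON
#' @param call_obj a [make_call()] result.
#' @param path optional output path; if missing, the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
specificity_call_json <- function(call_obj, path = NULL) {
  stopifnot(inherits(call_obj, "specificity_call"))
  payload <- list(
    excluded_locants = call_obj$excluded_locants,
    ranked_attacks = lapply(seq_len(nrow(call_obj$ranked_attacks)), function(i) {
      list(label = call_obj$ranked_attacks$label[i],
           locants = call_obj$ranked_attacks$locants[[i]],
           share = call_obj$ranked_attacks$share[i])
    }),
    enantiomer_status = call_obj$enantiomer_status,
    notes = call_obj$notes)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
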