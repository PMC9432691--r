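# Seeded synthetic-data generators. Each generator emits data with the
# statistical structure the corresponding analysis stage assumes, together
# with a machine-readable truth record, so recovery can be tested end to end
# without any external data.

# run code with a local, seeded RNG without disturbing the caller's stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Default truth weights for the peak-table generator
#'
#' Position-attack weights (1/h before scaling) expressing a dominant
#' 6-attack with minor 4-, 5- and 1/3-attacks and a spared 2-position —
#' the profile of a D6-dominant MINPP-style phytase.
#' @return named numeric of length 6.
#' @export
default_truth_weights <- function() {
  c(`1` = 0.5, `2` = 0, `3` = 0.5, `4` = 1, `5` = 1, `6` = 4)
}

#' Generate a synthetic HPLC peak table
#'
#' Simulates sequential phytate degradation under known ("truth") attack
#' weights, collapses species onto achiral co-elution classes, merges
#' monophosphates into the solvent-front signal (they co-elute with Pi on
#' this column type), scales to arbitrary area units and applies
#' multiplicative lognormal noise. Zero (absent-class) areas stay exactly
#' zero under multiplicative noise.
#'
#' @param seed integer RNG seed.
#' @param weights named truth attack weights (1/h), names `"1"`..`"6"`;
#'   default [default_truth_weights()].
#' @param forbidden_locants locants the simulated enzyme never attacks;
#'   default the zero-weight locants of `weights`.
#' @param rate_scale global multiplier on the weights (default 0.15,
#'   giving substantial but incomplete degradation of a 5 mM substrate over
#'   8 h).
#' @param level_scale optional level multipliers (see [rate_model()]).
#' @param timepoints sampling times in hours (default 0.5, 2, 4, 8).
#' @param initial_insp6 starting substrate concentration, mM (default 5).
#' @param noise `"none"` or `"multiplicative_lognormal"`.
#' @param noise_sd sd of log-areas under multiplicative noise (default 0.05).
#' @param response_factor area units per mM (default 100).
#' @param merge_insp1 merge InsP1 into the solvent front (default TRUE).
#' @return list with `peaks` (data.frame `time_h`, `class`, `area`) and
#'   `truth` (list: scaled weights, forbidden locants, rate model settings,
#'   seed).
#' @export
gen_peak_table <- function(seed = 1,
                           weights = default_truth_weights(),
                           forbidden_locants = NULL,
                           rate_scale = 0.15,
                           level_scale = NULL,
                           timepoints = c(0.5, 2, 4, 8),
                           initial_insp6 = 5,
                           noise = c("multiplicative_lognormal", "none"),
                           noise_sd = 0.05,
                           response_factor = 100,
                           merge_insp1 = TRUE) {
  noise <- match.arg(noise)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (is.null(names(weights))) names(weights) <- as.character(seq_along(weights))
  if (is.null(forbidden_locants)) {
    forbidden_locants <- as.integer(names(weights)[weights == 0])
  }
  w <- weights * rate_scale
  w[as.character(forbidden_locants)] <- 0
  net <- build_network(phospho_state(1:6), forbidden_locants)
  rm <- rate_model(w, level_scale = level_scale)
  tc <- simulate_network(net, rm, initial = initial_insp6,
                         times = sort(unique(c(0, timepoints))))
  ct <- class_timecourse(tc, merge_insp1 = merge_insp1)
  ct <- ct[ct$time_h %in% timepoints, ]
  peaks <- data.frame(time_h = ct$time_h, class = ct$class,
                      area = ct$abundance * response_factor,
                      stringsAsFactors = FALSE)
  # a real chromatogram records absent first-generation peaks as zero area:
  # emit explicit zero rows for product classes the truth never produces
  fg_classes <- unique(vapply(1:6, function(p) {
    canonical_class(phospho_state(setdiff(1:6, p)))$display_name
  }, character(1)))
  absent <- setdiff(fg_classes, unique(peaks$class))
  if (length(absent)) {
    zero_rows <- expand.grid(time_h = timepoints, class = absent,
                             stringsAsFactors = FALSE)
    zero_rows$area <- 0
    peaks <- rbind(peaks, zero_rows)
    peaks <- peaks[order(peaks$time_h, peaks$class), ]
  }
  if (noise == "multiplicative_lognormal" && noise_sd > 0) {
    peaks$area <- .with_seed(seed,
      peaks$area * exp(stats::rnorm(nrow(peaks), 0, noise_sd)))
  }
  rownames(peaks) <- NULL
  list(peaks = peaks,
       truth = list(weights = w, weights_unscaled = weights,
                    forbidden_locants = forbidden_locants,
                    rate_scale = rate_scale, level_scale = level_scale,
                    timepoints = timepoints, initial_insp6 = initial_insp6,
                    noise = noise, noise_sd = noise_sd,
                    response_factor = response_factor,
                    merge_insp1 = merge_insp1, seed = seed))
}

#' Generate a synthetic substrate-inhibition rate table
#'
#' Rates from `v = Vmax*S/(Km + S(1 + S/Ki))` at a log-spaced concentration
#' grid (default: twelve points spanning 12.5-3750 uM, i.e. 0.0125-3.75 mM)
#' with optional multiplicative lognormal noise.
#'
#' @param seed integer RNG seed.
#' @param Vmax,Km,Ki truth parameters (defaults 228 U/mg, 0.65 mM, 2.23 mM).
#' @param concentrations substrate grid in mM; default twelve log-spaced
#'   points from 0.0125 to 3.75.
#' @param noise_sd sd of log-rates (0 = noise-free).
#' @return list with `data` (data.frame `S_mM`, `v`) and `truth`.
#' @export
gen_kinetics_table <- function(seed = 1, Vmax = 228, Km = 0.65, Ki = 2.23,
                               concentrations = exp(seq(log(0.0125), log(3.75),
                                                        length.out = 12)),
                               noise_sd = 0) {
  if (any(concentrations <= 0)) stop("concentrations must be positive", call. = FALSE)
  v <- rate_substrate_inhibition(concentrations, Vmax, Km, Ki)
  if (noise_sd > 0) {
    v <- .with_seed(seed, v * exp(stats::rnorm(length(v), 0, noise_sd)))
  }
  list(data = data.frame(S_mM = concentrations, v = v),
       truth = list(Vmax = Vmax, Km = Km, Ki = Ki,
                    S_opt = sqrt(Km * Ki), noise_sd = noise_sd, seed = seed))
}

#' Generate a synthetic qPCR Ct table
#'
#' Reference-gene Ct values scatter around a baseline; target Ct values are
#' shifted per condition by `log2(1/fold)` relative to the control, so the
#' expected `2^-ddCt` fold change equals the planted fold.
#'
#' @param seed integer RNG seed.
#' @param folds named numeric of truth fold changes per condition; the first
#'   entry is taken as the control (its fold should be 1). Default emulates
#'   repression of a phytase gene in minimal media by phosphate (1/2.6) and
#'   phytate (1/7.5).
#' @param n replicates per condition (default 9).
#' @param sd_ct replicate sd of Ct values in cycles (default 0.3).
#' @param base_ct_reference,base_ct_target baseline Ct values.
#' @return list with `data` (data.frame `condition`, `replicate`,
#'   `ct_target`, `ct_reference`) and `truth`.
#' @export
gen_expression_table <- function(seed = 1,
                                 folds = c(MM = 1, `MM+Pi` = 1 / 2.6,
                                           `MM+InsP6` = 1 / 7.5),
                                 n = 9, sd_ct = 0.3,
                                 base_ct_reference = 16,
                                 base_ct_target = 20) {
  if (any(folds <= 0)) stop("fold changes must be positive", call. = FALSE)
  if (n < 3) stop("need >= 3 replicates per condition", call. = FALSE)
  .with_seed(seed, {
    rows <- lapply(names(folds), function(cond) {
      shift <- log2(1 / folds[[cond]]) - log2(1 / folds[[1]])
      data.frame(condition = cond, replicate = seq_len(n),
                 ct_target = base_ct_target + shift + stats::rnorm(n, 0, sd_ct),
                 ct_reference = base_ct_reference + stats::rnorm(n, 0, sd_ct),
                 stringsAsFactors = FALSE)
    })
    data <- do.call(rbind, rows)
    rownames(data) <- NULL
    list(data = data,
         truth = list(folds = folds, control = names(folds)[1], n = n,
                      sd_ct = sd_ct, seed = seed))
  })
}

#' Generate synthetic protein FASTA records with planted motifs
#'
#' Random background sequences with motif instances planted at recorded
#' positions (degenerate motif positions are instantiated to a concrete
#' residue, recorded in the truth).
#'
#' @param seed integer RNG seed.
#' @param n_records number of records.
#' @param length sequence length (>= longest planted motif + position).
#' @param planted named list per record index: list of `list(motif =
#'   expression, at = position)`; or a single such list recycled. Default:
#'   plant `"RHGSRGL"` at position 100 in every record.
#' @param path optional file to write (FASTA); if `NULL`, records are only
#'   returned.
#' @return list with `records` (list of `protein_record`) and `truth`
#'   (planted positions and realized motif text per record).
#' @export
gen_fasta <- function(seed = 1, n_records = 2, length = 300,
                      planted = list(list(motif = "RHGSRGL", at = 100)),
                      path = NULL) {
  if (!is.null(planted) && length(planted) && is.list(planted[[1]]) &&
      !is.null(planted[[1]]$motif)) {
    planted <- rep(list(planted), n_records)  # same plan for every record
  }
  .with_seed(seed, {
    records <- list(); truth <- list()
    for (r in seq_len(n_records)) {
      chars <- sample(.AA_CODES, length, replace = TRUE)
      plan <- if (r <= length(planted)) planted[[r]] else list()
      placed <- list()
      for (pl in plan) {
        sets <- .parse_motif(pl$motif)
        L <- base::length(sets)
        if (pl$at < 1 || pl$at + L - 1L > length) {
          stop("cannot place motif ", sQuote(pl$motif), " at ", pl$at,
               " in a sequence of length ", length, call. = FALSE)
        }
        realized <- vapply(sets, function(s) s[sample.int(base::length(s), 1)],
                           character(1))
        chars[pl$at:(pl$at + L - 1L)] <- realized
        placed[[base::length(placed) + 1L]] <- list(
          motif = pl$motif, at = pl$at, text = paste(realized, collapse = ""))
      }
      records[[r]] <- structure(list(id = sprintf("synthetic_%03d", r),
                                     desc = "synthetic protein with planted motifs",
                                     sequence = paste(chars, collapse = "")),
                                class = "protein_record")
      truth[[r]] <- placed
    }
    if (!is.null(path)) write_fasta(records, path)
    list(records = records, truth = list(planted = truth, seed = seed))
  })
}

#' Generate a toy PDB structure around a ligand phosphorus atom
#'
#' Places a single ligand phosphorus at the origin and one-atom residues
#' (CA) at the requested distances in deterministic pseudo-random
#' directions. Useful for validating distance-cutoff pocket rules.
#'
#' @param seed integer RNG seed (directions only; distances are exact).
#' @param distances numeric vector of residue distances in Angstrom.
#' @param path optional output PDB file.
#' @return list with `lines` (PDB text), `truth` (data.frame `resno`,
#'   `distance`), and `path` (if written).
#' @export
gen_toy_structure <- function(seed = 1, distances = c(3.0, 4.9, 5.1),
                              path = NULL) {
  .with_seed(seed, {
    dirs <- matrix(stats::rnorm(3 * length(distances)), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    xyz <- dirs * distances
    fmt_atom <- function(serial, name, resname, chain, resno, x, y, z,
                         record = "ATOM", element) {
      sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              record, serial, name, resname, chain, resno, x, y, z, 1.0, 0.0,
              element)
    }
    lines <- character()
    for (i in seq_along(distances)) {
      lines <- c(lines, fmt_atom(i, "CA", "ALA", "A", i,
                                 xyz[i, 1], xyz[i, 2], xyz[i, 3],
                                 record = "ATOM", element = "C"))
    }
    lines <- c(lines,
               fmt_atom(length(distances) + 1L, "P1", "IHP", "B", 900,
                        0, 0, 0, record = "HETATM", element = "P"),
               "END")
    if (!is.null(path)) writeLines(lines, path)
    list(lines = lines,
         truth = data.frame(resno = seq_along(distances), distance = distances),
         path = path)
  })
}

#' Preset kinase-assay evidence for InsP5 enantiomer discrimination
#'
#' Evidence object for the classic discrimination assay with a kinase that
#' pyrophosphorylates InsP6 and D-Ins(1,2,3,4,5)P5 (InsP5 6-OH) but not
#' D-Ins(1,2,3,5,6)P5 (InsP5 4-OH). Published control yields: ~0.90 for
#' InsP6, ~0.58 for the pure D-Ins(1,2,3,4,5)P5 standard; the unknown
#' phytase-product fraction converted at ~0.12.
#'
#' @param conversion observed conversion fraction of the unknown (default
#'   0.12).
#' @param threshold detection threshold (default 0.05).
#' @return a [kinase_evidence].
#' @export
itpk1_evidence <- function(conversion = 0.12, threshold = 0.05) {
  kinase_evidence(
    accepted_substrates = list("D-Ins(1,2,3,4,5,6)P6", "D-Ins(1,2,3,4,5)P5"),
    rejected_substrates = list("D-Ins(1,2,3,5,6)P5"),
    observed_conversion_fraction = conversion,
    detection_threshold = threshold)
}

#' Reference control conversion yields of the discrimination kinase assay
#' @return named numeric: conversion fractions for the InsP6 positive
#'   control, the pure D-Ins(1,2,3,4,5)P5 standard, and the rejected
#'   D-Ins(1,2,3,5,6)P5 negative control.
#' @export
itpk1_control_yields <- function() {
  c(InsP6 = 0.90, D_Ins12345_P5 = 0.58, D_Ins12356_P5 = 0.0)
}

#' Write a peak table as delimited text
#' @param peaks data.frame `time_h`, `class`, `area`.
#' @param path output path (tab-separated with header).
#' @return invisibly, the path.
#' @export
write_peak_table <- function(peaks, path) {
  validate_peak_table(peaks)
  utils::write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak table from delimited text
#' @param path tab- or comma-separated file with header `time_h`, `class`,
#'   `area`.
#' @return validated data.frame.
#' @export
read_peak_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  peaks <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  validate_peak_table(peaks)
  peaks
}

# Deterministic stand-in built once by seeded construction: background
# residues drawn from typical globular-protein composition, the five
# diagnostic motifs planted, composition then adjusted to the published
# theoretical average mass of the modelled enzyme (58.57 kDa).
.SYNTHETIC_MINPP_SEQ <- paste0(
  "NPSCHCTYPNQWLHEDQRMARNYPCHFQKRYSVLGGEMWRHGSRGLIDVQIEYDLIMSHWMMMFNPYKTNYHVFKQEMDM",
  "PNIRLVFAECFYDMKFHSQSVDPEHMIYNCPFMLNWSEALFPRIGTDAVNHQLFLPGGFSAKVVRKIRAPMAANKWRYRY",
  "TCDRDTDTSQSVRGDNHDKERFYFFWLMMEWKAMITGEPKCNQVSPCPELYNEFHYTLGWHLERAKINNSCVTADQARVD",
  "YHPHLEPYCNSSCIAIDCSVRNWKMNNIWANDYLMKVPNHFCYESELCGYSSVFYLTFEHAEISAGNAGPYVDKNKSWEY",
  "VSCGSPGGRDAAACDEEIDWVVTSCVTGNAEGWVTSEERMMNQCGKKMDKQSEQMSEFLPMFIKWNSRAIETIIIGRALY",
  "CRLLDTTKPEGQGCAGSVNMTWWTHVGSFPCDESVLPLNDMLWSPQFWFRSSTQWIVDRTYAEAKVEEKMSFCRGIYPFK",
  "LATFQQILSMELCKVSWKSE")

#' Synthetic stand-in for a soil MINPP phytase protein
#'
#' A SYNTHETIC 500-residue protein record (not a natural sequence): random
#' background with the five diagnostic motifs planted (the MINPP
#' heptapeptide variant RHGSRGL, the HAE proton-donor tripeptide, the
#' MINPP-specific PMAAN and LYNE motifs and the U-loop tetrapeptide DAAA)
#' and residue composition adjusted so the theoretical average mass matches
#' the 58.57 kDa reported for the enzyme the package models. Useful as a
#' self-contained positive control for [scan_motifs()], [classify_phytase()]
#' and [theoretical_mass()].
#'
#' @return a `protein_record`.
#' @examples
#' theoretical_mass(synthetic_minpp_protein())  # 58.57
#' @export
synthetic_minpp_protein <- function() {
  structure(list(id = "synthetic_minpp",
                 desc = "synthetic MINPP-like stand-in (planted motifs, 58.57 kDa)",
                 sequence = .SYNTHETIC_MINPP_SEQ),
            class = "protein_record")
}
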