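# Orchestration: run the full analysis (generate -> simulate -> infer ->
# fit -> report) from a single configuration, with seeded reproducibility.

# small stable FNV-1a hash of a configuration (hex string); avoids an
# external digest dependency
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' @param seed integer seed recorded in every report and used by every
#'   stochastic stage.
#' @param out_dir output directory (created if needed); `NULL` = no files.
#' @param stages character vector of stages to run, in dependency order, out
#'   of `"specificity"`, `"kinetics"`, `"expression"`, `"motifs"`.
#' @param absence_floor fraction for [exclude_by_absence()].
#' @param kinase_threshold detection threshold for [itpk1_evidence()].
#' @param kinase_conversion observed conversion of the unknown InsP5
#'   fraction.
#' @param peak_args list of overrides for [gen_peak_table()].
#' @param kinetics_args list of overrides for [gen_kinetics_table()].
#' @param expression_args list of overrides for [gen_expression_table()].
#' @param fit_weights also run [fit_preferences()] in the specificity stage
#'   (slower); default FALSE.
#' @return a named list (class `run_config`).
#' @export
run_config <- function(seed = 1, out_dir = NULL,
                       stages = c("specificity", "kinetics", "expression",
                                  "motifs"),
                       absence_floor = 0.01,
                       kinase_threshold = 0.05,
                       kinase_conversion = 0.12,
                       peak_args = list(),
                       kinetics_args = list(),
                       expression_args = list(),
                       fit_weights = FALSE) {
  bad <- setdiff(stages, c("specificity", "kinetics", "expression", "motifs"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(seed = seed, out_dir = out_dir, stages = stages,
                 absence_floor = absence_floor,
                 kinase_threshold = kinase_threshold,
                 kinase_conversion = kinase_conversion,
                 peak_args = peak_args, kinetics_args = kinetics_args,
                 expression_args = expression_args,
                 fit_weights = fit_weights),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(run_config, vals)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order on seeded synthetic
#' data (or caller-supplied tables via the `*_args` overrides):
#' `"specificity"` generates a peak table, runs exclusion, attack ranking,
#' kinase-evidence disambiguation and assembles a [make_call()];
#' `"kinetics"` generates rate data and fits the substrate-inhibition model;
#' `"expression"` generates a Ct table and runs [expression_analysis()];
#' `"motifs"` scans the bundled synthetic MINPP stand-in. Every report
#' embeds the seed and a configuration hash. If `out_dir` is set, reports
#' are written there (delimited text + JSON summary).
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @param peaks optional externally supplied peak table for the specificity
#'   stage (skips generation).
#' @return object of class `pipeline_result`: list with one element per
#'   executed stage plus `seed`, `config_hash`, `stages`.
#' @export
run_pipeline <- function(config = run_config(), peaks = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (length(config$stages) == 0) {
    warning("empty stage list; nothing to do")
    hashable <- unclass(config); hashable$out_dir <- NULL
    return(structure(list(seed = config$seed,
                          config_hash = .config_hash(hashable),
                          stages = character()),
                     class = "pipeline_result"))
  }
  hashable <- unclass(config)
  hashable$out_dir <- NULL  # volatile path; must not perturb the run identity
  out <- list(seed = config$seed,
              config_hash = .config_hash(hashable),
              stages = config$stages)
  dir_ok <- !is.null(config$out_dir)
  if (dir_ok) dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if ("specificity" %in% config$stages) {
    if (is.null(peaks)) {
      gen <- do.call(gen_peak_table, c(list(seed = config$seed),
                                       config$peak_args))
      peaks_use <- gen$peaks
      truth <- gen$truth
    } else {
      peaks_use <- validate_peak_table(peaks)
      truth <- NULL
    }
    parent <- phospho_state(1:6)
    excl <- exclude_by_absence(peaks_use, parent,
                               floor_frac = config$absence_floor)
    ranking <- rank_initial_attack(peaks_use, parent)
    top <- ranking$locants[[1]]
    enantio <- NULL
    if (length(top) == 2) {
      cand <- candidates_for_class(ranking$class[1])
      ev <- itpk1_evidence(conversion = config$kinase_conversion,
                           threshold = config$kinase_threshold)
      enantio <- enantio_disambiguate(cand, ev)
    }
    call_obj <- make_call(excl, ranking, enantio, parent = parent)
    pref <- NULL
    if (isTRUE(config$fit_weights)) {
      net <- build_network(parent, excl)
      pref <- fit_preferences(peaks_use, net)
    }
    out$specificity <- list(peaks = peaks_use, truth = truth, call = call_obj,
                            ranking = ranking, preference_fit = pref)
    if (dir_ok) {
      write_peak_table(peaks_use, file.path(config$out_dir, "peak_table.tsv"))
      specificity_call_json(call_obj,
                            file.path(config$out_dir, "specificity_call.json"))
    }
  }

  if ("kinetics" %in% config$stages) {
    gen <- do.call(gen_kinetics_table, c(list(seed = config$seed),
                                         config$kinetics_args))
    fit <- fit_substrate_inhibition(gen$data)
    out$kinetics <- list(data = gen$data, truth = gen$truth, fit = fit)
    if (dir_ok) {
      utils::write.table(gen$data, file.path(config$out_dir, "kinetics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(Vmax = fit$Vmax, Km = fit$Km, Ki = fit$Ki, S_opt = fit$S_opt,
             se = as.list(fit$se), rss = fit$rss),
        file.path(config$out_dir, "kinetics_fit.json"),
        auto_unbox = TRUE, digits = NA)
    }
  }

  if ("expression" %in% config$stages) {
    gen <- do.call(gen_expression_table, c(list(seed = config$seed),
                                           config$expression_args))
    res <- expression_analysis(gen$data, control = gen$truth$control)
    out$expression <- list(data = gen$data, truth = gen$truth, result = res)
    if (dir_ok) {
      utils::write.table(as.data.frame(res),
                         file.path(config$out_dir, "expression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("motifs" %in% config$stages) {
    rec <- synthetic_minpp_protein()
    hits <- scan_motifs(rec)
    cls <- classify_phytase(hits)
    out$motifs <- list(record_id = rec$id, hits = hits, classification = cls,
                       mass_kda = theoretical_mass(rec))
    if (dir_ok) {
      utils::write.table(hits, file.path(config$out_dir, "motif_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (dir_ok) {
    summary_js <- list(seed = out$seed, config_hash = out$config_hash,
                       stages = out$stages)
    if (!is.null(out$specificity)) {
      summary_js$excluded_locants <- out$specificity$call$excluded_locants
      summary_js$top_attack <- out$specificity$call$ranked_attacks$label[1]
      summary_js$enantiomer_status <- out$specificity$call$enantiomer_status
    }
    if (!is.null(out$kinetics)) {
      summary_js$kinetics <- list(Vmax = out$kinetics$fit$Vmax,
                                  Km = out$kinetics$fit$Km,
                                  Ki = out$kinetics$fit$Ki)
    }
    if (!is.null(out$expression)) {
      summary_js$fold_changes <- stats::setNames(
        as.list(out$expression$result$fold_change),
        out$expression$result$condition)
    }
    if (!is.null(out$motifs)) {
      summary_js$motif_class <- out$motifs$classification$class
      summary_js$mass_kda <- out$motifs$mass_kda
    }
    jsonlite::write_json(summary_js, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(out, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ", config ", x$config_hash, ")\n", sep = "")
  cat("stages:", paste(x$stages, collapse = ", "), "\n")
  if (!is.null(x$specificity)) { cat("\n"); print(x$specificity$call) }
  if (!is.null(x$kinetics)) { cat("\n"); print(x$kinetics$fit) }
  if (!is.null(x$expression)) { cat("\n"); print(x$expression$result) }
  if (!is.null(x$motifs)) {
    cat("\nMotif classification:", x$motifs$classification$class,
        sprintf("(%d hits; theoretical mass %.2f kDa)\n",
                nrow(x$motifs$hits), x$motifs$mass_kda))
  }
  invisible(x)
}
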