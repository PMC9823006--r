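#' Build a pipeline run configuration
#'
#' Collects every knob of the analysis in one validated object. Input is
#' either a built-in scenario name (synthetic data generated on the fly)
#' or a directory of peak-list files with a concentration table.
#'
#' @param scenario scenario name for synthetic input
#'   (see [default_scenario()]), or `NULL` when `peaklist_dir` is given.
#' @param peaklist_dir directory containing `point_*.list` Sparky files and
#'   a `concentrations.tsv` (`point`, `ligand_total`, `protein_total`), or
#'   `NULL` for synthetic input.
#' @param seed integer seed recorded in all outputs.
#' @param alpha 15N scaling factor.
#' @param max_step tracking step threshold (ppm, scaled).
#' @param overlap_tol overlap threshold (ppm, scaled).
#' @param rule significance rule (see [classify_significance()]).
#' @param fit_mode pooling mode (see [fit_binding()]).
#' @param structure_path optional coordinate file for CSP mapping.
#' @param chain chain painted/analysed when a structure is given.
#' @param out_dir output directory.
#' @param kd,final_ratio,n_binders optional scenario overrides (kd in mM).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(scenario = "fc14-like", peaklist_dir = NULL,
                       seed = 1L, alpha = 0.154, max_step = 0.05,
                       overlap_tol = 0.01, rule = "mean_plus_ksigma",
                       fit_mode = "per_residue_average",
                       structure_path = NULL, chain = "B",
                       out_dir = "csp_run", kd = NULL, final_ratio = NULL,
                       n_binders = NULL) {
  if (is.null(scenario) && is.null(peaklist_dir))
    stop("either a scenario or a peak-list directory must be given")
  for (v in c(alpha = alpha, max_step = max_step, overlap_tol = overlap_tol))
    if (v <= 0) stop("all thresholds must be positive")
  structure(list(scenario = scenario, peaklist_dir = peaklist_dir,
                 seed = as.integer(seed), alpha = alpha,
                 max_step = max_step, overlap_tol = overlap_tol,
                 rule = rule, fit_mode = fit_mode,
                 structure_path = structure_path, chain = chain,
                 out_dir = out_dir, kd = kd, final_ratio = final_ratio,
                 n_binders = n_binders),
            class = "run_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Keys match the arguments of [run_config()]; numeric values are
#' converted. Unknown keys are an error.
#'
#' @param path config file path.
#' @param overrides named list of values that win over the file.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  known <- names(formals(run_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- stats::setNames(as.list(vals), keys)
  numeric_keys <- c("seed", "alpha", "max_step", "overlap_tol", "kd",
                    "final_ratio", "n_binders")
  for (k in intersect(names(args), numeric_keys))
    args[[k]] <- as.numeric(args[[k]])
  for (k in names(overrides)) args[[k]] <- overrides[[k]]
  do.call(run_config, args)
}

load_peaklist_series <- function(dir, alpha) {
  conc_path <- file.path(dir, "concentrations.tsv")
  if (!file.exists(conc_path))
    stop("concentration table not found: ", conc_path)
  conc <- utils::read.table(conc_path, header = TRUE, sep = "\t")
  files <- file.path(dir, sprintf("point_%02d.list", conc$point))
  pls <- lapply(seq_len(nrow(conc)), function(i)
    read_peak_list(files[i], dialect = "sparky-list",
                   point_index = conc$point[i],
                   ligand_total = conc$ligand_total[i],
                   protein_total = conc$protein_total[i]))
  titration_series(pls)
}

#' Run the full CSP titration analysis pipeline
#'
#' Stages: obtain the titration series (simulate a scenario or load peak
#' lists), transfer apo assignments across the series implicitly through
#' chained tracking, track peaks, compute and classify endpoint CSPs,
#' select reporters, fit the binding isotherm, and (when a structure is
#' given) paint the CSPs onto it and test the spatial clustering of the
#' significant residues. Every stage logs one line; all products plus a
#' machine-readable `summary.json` land in the output directory. The run
#' is deterministic given the seed.
#'
#' @param config a `"run_config"` (or arguments forwarded to
#'   [run_config()]).
#' @param quiet suppress stage logging.
#' @return Invisibly, a list with the output directory, the summary, and
#'   the fitted `"csp_fit"` object.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$peaklist_dir)) {
      series <- load_peaklist_series(config$peaklist_dir, config$alpha)
      truth <- NULL
      log_stage(stage, "loaded %d peak lists from %s", length(series),
                config$peaklist_dir)
    } else {
      truth <- default_scenario(config$scenario, seed = config$seed,
                                kd = config$kd,
                                final_ratio = config$final_ratio,
                                n_binders = config$n_binders,
                                alpha = config$alpha)
      series <- simulate_titration(truth)
      write_ground_truth(truth, file.path(out, "ground_truth.json"))
      for (k in seq_along(series$points))
        write_peak_list(series$points[[k]],
                        file.path(out, sprintf("point_%02d.list", k - 1L)))
      log_stage(stage, "simulated scenario '%s' (seed %d, %d points)",
                config$scenario, config$seed, length(series))
    }

    stage <- "track"
    tracks <- track_series(series, alpha = config$alpha,
                           max_step = config$max_step)
    tracks <- flag_overlap(series, tracks,
                           overlap_tol = config$overlap_tol)
    utils::write.table(as.data.frame(tracks),
                       file.path(out, "tracks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage(stage, "%d residues tracked (%d complete, %d overlapped; max_step %g)",
              length(tracks$residues), sum(tracks$status == "complete"),
              sum(tracks$overlapped), config$max_step)

    stage <- "csp"
    table <- classify_significance(tracks, rule = config$rule)
    write_csp_table(table, file.path(out, "csp_table.tsv"))
    thr <- csp_thresholds(table)
    log_stage(stage, "mean %.4f ppm, sigma %.4f ppm, %d at 2sigma (rule %s)",
              thr[["mean"]], thr[["sigma"]], sum(table$class == "2sigma"),
              config$rule)

    stage <- "fit"
    reporters <- select_reporters(table, tracks)
    fit <- fit_binding(tracks, reporters, mode = config$fit_mode)
    write_fit_report(fit, out)
    log_stage(stage, "K_D = %.3g +/- %.2g uM over n = %d reporters (%s)",
              fit$kd_mean_uM, fit$kd_sd_uM, fit$n, config$fit_mode)

    clustering <- NULL
    if (!is.null(config$structure_path)) {
      stage <- "map"
      model <- read_structure(config$structure_path)
      paint_csp(model, table, chain = config$chain,
                path = file.path(out, "csp_painted.pdb"))
      sig <- table$residue[table$class == "2sigma"]
      if (length(intersect(sig, chain_ca(model, config$chain)$resno)) >= 3) {
        clustering <- patch_clustering(model, config$chain, sig,
                                       seed = config$seed)
        clustering$null <- NULL
      }
      log_stage(stage, "painted chain %s%s", config$chain,
                if (is.null(clustering)) ""
                else sprintf("; clustering p = %.4g", clustering$p_value))
    }

    stage <- "summary"
    summary <- list(
      seed = config$seed,
      scenario = config$scenario,
      parameters = list(alpha = config$alpha, max_step = config$max_step,
                        overlap_tol = config$overlap_tol,
                        rule = config$rule, fit_mode = config$fit_mode),
      n_tracked = length(tracks$residues),
      n_complete = sum(tracks$status == "complete"),
      n_overlapped = sum(tracks$overlapped),
      csp_mean_ppm = unname(thr[["mean"]]),
      csp_sigma_ppm = unname(thr[["sigma"]]),
      residues_1sigma = table$residue[table$class == "1sigma"],
      residues_2sigma = table$residue[table$class == "2sigma"],
      reporters = reporters,
      kd_mean_uM = fit$kd_mean_uM,
      kd_sd_uM = fit$kd_sd_uM,
      n = fit$n,
      clustering = clustering
    )
    if (!is.null(truth)) summary$true_kd_uM <- truth$model$kd * 1000
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(out_dir = out, summary = summary, fit = fit, tracks = tracks,
         table = table)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
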