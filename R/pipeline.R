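#' Run configuration for the four-step assessment pipeline
#'
#' Collects the paths and options of one end-to-end run: the image-quality
#' library (step 1), nodule/template specs (step 2), the protocol grid over
#' which e' is evaluated (step 3), and the calibration arm relating e' to
#' PRC (step 4). Configs round-trip through YAML unchanged.
#'
#' @param library path to a library directory written by
#'   [write_iq_library()], or `"synthetic"` to build the parametric library.
#' @param nodules list of [nodule_model()]s, or paths to YAML/JSON specs.
#' @param protocols list with `dose_fractions`, `thicknesses_mm`, `recons`.
#' @param out_dir output directory for run artifacts.
#' @param seed master seed for every stochastic stage.
#' @param exclude_dc DC-bin policy passed to [estimability_index()].
#' @param calibrate run the desk-scale virtual precision experiment and fit
#'   the PRC calibration (slower).
#' @param experiment options for the calibration experiment, see
#'   [virtual_precision_experiment()].
#' @param software label under which the calibration is stored.
#' @return a `run_config` list.
#' @export
run_config <- function(library = "synthetic", nodules, protocols, out_dir,
                       seed = 42, exclude_dc = TRUE, calibrate = FALSE,
                       experiment = list(), software = "threshold-standin") {
  cfg <- list(library = library, nodules = nodules, protocols = protocols,
              out_dir = out_dir, seed = as.integer(seed),
              exclude_dc = isTRUE(exclude_dc), calibrate = isTRUE(calibrate),
              experiment = experiment, software = software)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of [run_config()]; nodules may be
#'   inline specs (`diameter_mm`, `contrast_hu`, ...) or paths.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!identical(cfg$library, "synthetic") && !dir.exists(cfg$library)) {
    stop("library path does not exist: ", cfg$library, call. = FALSE)
  }
  if (!length(cfg$nodules)) stop("no nodules configured", call. = FALSE)
  p <- cfg$protocols
  if (is.null(p$dose_fractions) || is.null(p$thicknesses_mm) || is.null(p$recons)) {
    stop("protocols must define dose_fractions, thicknesses_mm and recons",
         call. = FALSE)
  }
  invisible(cfg)
}

resolve_nodules <- function(nodules) {
  lapply(nodules, function(nd) {
    if (inherits(nd, "nodule_model")) return(nd)
    if (is.character(nd)) return(read_nodule_spec(nd))
    nodule_model(diameter_mm = nd$diameter_mm, contrast_hu = nd$contrast_hu,
                 edge_width_mm = nd$edge_width_mm %||% 0, label = nd$label)
  })
}

#' Run the four-step e'-based precision assessment
#'
#' Step 1 acquires the (NPS, TTF) library; step 2 models the task and
#' template functions for each nodule; step 3 evaluates e' across the
#' protocol grid; step 4 (optional) runs the desk-scale virtual
#' repeatability experiment, fits the logarithmic calibration of PRC against
#' the imprecision predictor 1/e', and attaches predicted PRC to every
#' protocol row. Artifacts (`results.csv`, `calibration.json`, `run.log`)
#' are stamped with a configuration hash and the package version; two runs
#' with identical config and seed produce identical results files.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with `results` (the [evaluate_protocols()]
#'   tibble, plus `prc_pred` when calibrated), `calibration` (or `NULL`),
#'   `experiment` (or `NULL`) and the artifact paths.
#' @export
run_pipeline <- function(cfg) {
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  cfg_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  logline <- function(...) {
    cat(sprintf("ts=%s %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                sprintf(...)),
        file = log_path, append = TRUE)
  }
  cat(sprintf("config_hash=%s package_version=%s\n", cfg_hash,
              as.character(utils::packageVersion("estimact"))),
      file = log_path)

  step <- "library"
  out <- tryCatch({
    logline("stage=%s status=start", step)
    lib <- if (identical(cfg$library, "synthetic")) {
      build_synthetic_library(
        dose_fractions = cfg$protocols$dose_fractions,
        thicknesses_mm = cfg$protocols$thicknesses_mm,
        recons = cfg$protocols$recons
      )
    } else {
      read_iq_library(cfg$library)
    }
    logline("stage=%s status=done entries=%d", step, length(lib$entries))

    step <- "task"
    nods <- resolve_nodules(cfg$nodules)
    logline("stage=%s status=done nodules=%d", step, length(nods))

    step <- "eprime"
    grid <- protocol_grid(cfg$protocols$dose_fractions,
                          cfg$protocols$thicknesses_mm, cfg$protocols$recons)
    results <- evaluate_protocols(lib, nods, grid, exclude_dc = cfg$exclude_dc)
    logline("stage=%s status=done rows=%d", step, nrow(results))

    calibration <- NULL
    experiment <- NULL
    if (cfg$calibrate) {
      step <- "precision"
      ex_args <- utils::modifyList(
        list(nodules = nods, seed = cfg$seed),
        cfg$experiment
      )
      experiment <- do.call(virtual_precision_experiment, ex_args)
      calibration <- fit_calibration(experiment$summary, x = inv_e_prime,
                                     y = prc_pct, software = cfg$software)
      results$prc_pred <- predict_prc(results$inv_e_prime, calibration)
      write_calibration(calibration, file.path(cfg$out_dir, "calibration.json"))
      logline("stage=%s status=done r_squared=%.4f", step, calibration$r_squared)
    }

    res_path <- file.path(cfg$out_dir, "results.csv")
    meta <- sprintf("# estimact %s config=%s",
                    as.character(utils::packageVersion("estimact")), cfg_hash)
    writeLines(meta, res_path)
    suppressWarnings(utils::write.table(results, res_path, sep = ",",
                                        row.names = FALSE, append = TRUE,
                                        qmethod = "double"))
    logline("stage=results status=done path=%s", res_path)
    list(results = results, calibration = calibration, experiment = experiment,
         paths = list(results = res_path, log = log_path,
                      calibration = if (cfg$calibrate) {
                        file.path(cfg$out_dir, "calibration.json")
                      }))
  }, error = function(e) {
    logline("stage=%s status=error message=%s", step, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", step, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(out)
}

#' Command-line entry point
#'
#' A thin argv-level wrapper (plain flag parsing, no extra dependencies)
#' used by the `inst/cli/estimact.R` script:
#' `estimact run --config run.yaml` executes [run_pipeline()];
#' `estimact prc --in volumes.csv` computes a pooled PRC from a measurements
#' CSV (`case_id`, `volume_mm3`); `estimact predict --model cal.json
#' --predictor 0.7` evaluates a stored calibration.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return exit status, 0 on success (invisibly).
#' @export
estimact_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message("usage: estimact <run|prc|predict> [options]")
    return(invisible(1L))
  }
  cmd <- argv[1]
  opts <- argv[-1]
  getopt <- function(flag, required = TRUE) {
    i <- which(opts == flag)
    if (!length(i) || i == length(opts)) {
      if (required) stop("missing option ", flag, call. = FALSE)
      return(NULL)
    }
    opts[i + 1]
  }
  status <- switch(cmd,
    run = {
      cfg <- read_run_config(getopt("--config"))
      run_pipeline(cfg)
      0L
    },
    prc = {
      df <- utils::read.csv(getopt("--in"))
      out <- percent_repeatability_coefficient(df)
      cat(sprintf("prc_pct=%.6g sigma_w_pct=%.6g n_cases=%d\n",
                  out$prc_pct, out$sigma_w_pct, out$n_cases))
      0L
    },
    predict = {
      model <- read_calibration(getopt("--model"))
      x <- as.numeric(getopt("--predictor"))
      cat(sprintf("prc_pred=%.6g\n", predict_prc(x, model)))
      0L
    },
    {
      message("unknown command: ", cmd)
      1L
    }
  )
  invisible(status)
}
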