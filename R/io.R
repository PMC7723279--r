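# Trial-log CSV schema. Missing demonstration/choice/outcome are written as
# empty fields. p_a/p_b (the generator's ground-truth win probabilities) are
# optional extra columns: present in simulated logs, absent in empirical ones.
TRIAL_COLUMNS <- c("subject_id", "session", "block", "trial_index",
                   "condition", "context_id", "trial_type", "option_a",
                   "option_b", "demonstration", "choice", "outcome")

#' Write a trial log
#'
#' @param trials Trial records ([make_schedule()] / [simulate_agent()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  keep <- c(TRIAL_COLUMNS, intersect(c("p_a", "p_b"), names(trials)))
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial data lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(trials[, keep], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial log
#'
#' Reads a trial-log CSV, validates the schema (column set, trial types,
#' demonstration present on observational trials, outcomes in `{+1, -1}`),
#' sorts chronologically within subject, and splits into per-subject
#' datasets.
#'
#' @param path CSV path written by [write_trials()] (or following the same
#'   schema).
#' @return Named list of per-subject `data.frame`s.
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(subject_id = "character",
                                           context_id = "character"))
  for (col in c("demonstration", "choice")) {
    if (col %in% names(trials)) {
      trials[[col]] <- as.character(trials[[col]])
      trials[[col]][!is.na(trials[[col]]) & trials[[col]] == ""] <- NA_character_
    }
  }
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial log lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad_type <- which(!trials$trial_type %in% c("observational", "private"))
  if (length(bad_type) > 0L) {
    stop("invalid trial_type at row ", bad_type[1], " (column trial_type)")
  }
  obs <- trials$trial_type == "observational"
  bad_demo <- which(obs & (is.na(trials$demonstration) |
                             !(trials$demonstration == trials$option_a |
                                 trials$demonstration == trials$option_b)))
  if (length(bad_demo) > 0L) {
    stop("observational trial without valid demonstration at row ",
         bad_demo[1], " (column demonstration)")
  }
  bad_out <- which(!obs & !is.na(trials$outcome) &
                     !trials$outcome %in% c(-1, 1))
  if (length(bad_out) > 0L) {
    stop("outcome outside {+1, -1} at row ", bad_out[1], " (column outcome)")
  }
  subjects <- unique(trials$subject_id)
  out <- lapply(subjects, function(s) {
    d <- trials[trials$subject_id == s, ]
    d[order(d$session, d$block, d$trial_index), ]
  })
  stats::setNames(out, subjects)
}

#' Read a pipeline configuration
#'
#' YAML document with a `task` section (passed to [task_config()]) and
#' optional `cohort` (`n_subjects`, `conditions`), `models` (character
#' vector of ids), and `fitting` (`objective`, `n_restarts`) sections. An
#' annotated example ships with the package
#' (`system.file("extdata", "exp2_example.yaml", package = "socialrl")`).
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$task) || is.null(raw$task$experiment)) {
    stop("config must contain a 'task' section with an 'experiment' field")
  }
  task_args <- raw$task
  if (!is.null(task_args$obs_to_private_ratio)) {
    task_args$obs_to_private_ratio <- as.integer(task_args$obs_to_private_ratio)
  }
  cohort <- raw$cohort %||% list()
  cohort$n_subjects <- as.integer(cohort$n_subjects %||% 20L)
  models <- unlist(raw$models %||% list("RW2", "DB6", "MB9", "VS2"))
  bad <- setdiff(models, model_registry())
  if (length(bad) > 0L) stop("unknown model id(s) in config: ",
                             paste(bad, collapse = ", "))
  fitting <- raw$fitting %||% list()
  list(
    task_args = task_args, cohort = cohort, models = models,
    fit_opts = fit_options(objective = fitting$objective %||% "nll",
                           n_restarts = fitting$n_restarts %||% 10L),
    generate = raw$generate %||% list(model = "VS2", params = NULL)
  )
}

stage_seed <- function(master_seed, stage) {
  # deterministic per-stage child seeds, kept within 32-bit integer range
  offsets <- c(simulate = 11L, fit = 29L, compare = 47L,
               `recover-models` = 83L, `recover-params` = 131L,
               signatures = 197L)
  (as.integer(master_seed) * 1009L + offsets[[stage]]) %% 2147483647L
}

write_manifest <- function(out_dir, command, seed, stage_seeds, files, config) {
  manifest <- list(
    package = "socialrl",
    version = as.character(utils::packageVersion("socialrl")),
    command = command, master_seed = seed, stage_seeds = as.list(stage_seeds),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run a pipeline stage
#'
#' Executes one stage of the simulate / fit / compare workflow with seeded
#' reproducibility and writes its outputs plus a JSON run manifest
#' (seeds, package version, file checksums) to `out_dir`.
#'
#' Commands:
#' * `simulate`: generate a cohort of schedules and simulated agents
#'   (`trials.csv`).
#' * `fit`: fit the configured models to a trial log (`fits.csv`).
#' * `compare`: random-effects model selection on a fit table (`bms.csv`).
#' * `recover-models`: model-recovery confusion matrices
#'   (`recovery_frequency.csv`, `recovery_xp.csv`).
#' * `recover-params`: parameter-recovery correlations
#'   (`parameter_recovery.csv`).
#' * `signatures`: behavioral signature table for a trial log
#'   (`signatures.csv`).
#'
#' @param config Configuration list from [read_config()] (or a path to the
#'   YAML file).
#' @param command Stage to run.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; per-stage seeds are derived from it and recorded
#'   in the manifest.
#' @param trials_path,fits_path Inputs for the `fit`, `compare` and
#'   `signatures` stages.
#' @return Named list of written file paths (including the manifest),
#'   invisibly.
#' @export
run_pipeline <- function(config, command = c("simulate", "fit", "compare",
                                             "recover-models",
                                             "recover-params", "signatures"),
                         out_dir, seed = 1L, trials_path = NULL,
                         fits_path = NULL) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sseed <- stage_seed(seed, command)
  files <- list()

  if (command == "simulate") {
    gen_id <- config$generate$model %||% "VS2"
    spec <- model_spec(gen_id)
    cohort <- list()
    for (si in seq_len(config$cohort$n_subjects)) {
      cond <- if (!is.null(config$cohort$conditions)) {
        config$cohort$conditions[[((si - 1L) %% length(config$cohort$conditions)) + 1L]]
      } else config$task_args$condition %||% "SD"
      task_args <- config$task_args
      task_args$condition <- cond
      cfg <- do.call(task_config, task_args)
      sched <- make_schedule(cfg, seed = sseed + 2L * si,
                             subject_id = sprintf("s%03d", si))
      params <- if (is.null(config$generate$params)) {
        p <- param_set()
        p[spec$free] <- withr::with_seed(sseed + 2L * si + 1L,
                                         sample_prior_params(spec, 1L)[1L, ])
        p
      } else as_param_set(unlist(config$generate$params))
      cohort[[si]] <- simulate_agent(spec, params, sched,
                                     seed = sseed + 2L * si + 1L)
    }
    path <- file.path(out_dir, "trials.csv")
    write_trials(do.call(rbind, cohort), path)
    files$trials <- path
  } else if (command == "fit") {
    if (is.null(trials_path)) stop("fit requires trials_path")
    datasets <- read_trials(trials_path)
    opts <- config$fit_opts
    opts$seed <- sseed
    fits <- fit_cohort(config$models, datasets, opts)
    path <- file.path(out_dir, "fits.csv")
    utils::write.csv(fits, path, row.names = FALSE)
    files$fits <- path
  } else if (command == "compare") {
    if (is.null(fits_path)) stop("compare requires fits_path")
    fits <- utils::read.csv(fits_path, stringsAsFactors = FALSE)
    ev <- stats::reshape(fits[, c("subject_id", "model_id", "aic")],
                         direction = "wide", idvar = "subject_id",
                         timevar = "model_id")
    mat <- as.matrix(ev[, -1, drop = FALSE])
    colnames(mat) <- sub("^aic\\.", "", colnames(mat))
    bms <- rfx_bms(mat, seed = sseed)
    path <- file.path(out_dir, "bms.csv")
    utils::write.csv(data.frame(model_id = bms$models,
                                expected_frequency = bms$expected_frequency,
                                exceedance_probability = bms$exceedance_probability,
                                chance_level = bms$chance_level,
                                row.names = NULL), path, row.names = FALSE)
    files$bms <- path
  } else if (command == "recover-models") {
    cfg <- do.call(task_config, config$task_args)
    rep_ <- model_recovery(config$models, cfg,
                           n_subjects = config$cohort$n_subjects,
                           seed = sseed, fit_opts = config$fit_opts)
    for (nm in c("frequency", "xp")) {
      path <- file.path(out_dir, paste0("recovery_", nm, ".csv"))
      utils::write.csv(rep_[[nm]], path)
      files[[nm]] <- path
    }
  } else if (command == "recover-params") {
    cfg <- do.call(task_config, config$task_args)
    pr <- parameter_recovery(config$generate$model %||% "VS2", cfg,
                             n_subjects = config$cohort$n_subjects,
                             seed = sseed)
    path <- file.path(out_dir, "parameter_recovery.csv")
    utils::write.csv(pr$correlations, path, row.names = FALSE)
    files$parameter_recovery <- path
  } else if (command == "signatures") {
    if (is.null(trials_path)) stop("signatures requires trials_path")
    datasets <- read_trials(trials_path)
    tab <- do.call(rbind, lapply(names(datasets), function(nm) {
      cbind(subject_id = nm, signature_table(datasets[[nm]], source = "observed"))
    }))
    path <- file.path(out_dir, "signatures.csv")
    utils::write.csv(tab, path, row.names = FALSE)
    files$signatures <- path
  }

  files$manifest <- write_manifest(out_dir, command, seed,
                                   stats::setNames(sseed, command),
                                   files, config)
  invisible(files)
}
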