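# Shared I/O: the long-format trial CSV interchange format, YAML
# serialization of fitted objects, and the end-to-end pipeline driver.

.TRIAL_COLS <- c("patient_id", "arm", "dose_mg", "time_months", "visit_idx",
                 paste0("item", 1:7), "total", "qol_base", "bii_base",
                 "region")

#' Read a long-format trial CSV
#'
#' Validates the interchange schema (one row per patient-visit): item
#' scores in 0..5 or empty, nonnegative times, no duplicate
#' (patient, visit) rows, and — where a `total` column is present — that it
#' equals the item sum on complete rows. Validation failures name the
#' offending rows.
#'
#' @param path CSV path; lines starting with `#` are metadata comments.
#' @return A `trial_dataset` data.frame, row order preserved.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  miss <- setdiff(setdiff(.TRIAL_COLS, c("visit_idx", "total")), names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  for (j in 1:7) {
    col <- paste0("item", j)
    bad <- which(!is.na(df[[col]]) &
                   (df[[col]] < 0 | df[[col]] > 5 |
                      df[[col]] != round(df[[col]])))
    if (length(bad))
      stop("item score out of range 0..5 in column ", col, ", row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(df$time_months < 0))
    stop("negative time_months in row(s) ",
         paste(utils::head(which(df$time_months < 0), 5L), collapse = ", "),
         call. = FALSE)
  key <- paste(df$patient_id, df$time_months)
  if (anyDuplicated(key))
    stop("duplicate (patient, visit) row(s): ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "),
         call. = FALSE)
  if (!is.null(df$total)) {
    it <- as.matrix(df[paste0("item", 1:7)])
    complete <- rowSums(is.na(it)) == 0L
    bad <- which(complete & !is.na(df$total) & df$total != rowSums(it))
    if (length(bad))
      stop("total does not equal the item sum in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  class(df) <- c("trial_dataset", "data.frame")
  df
}

#' Write a trial dataset as CSV
#'
#' @param dataset a `trial_dataset`.
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(dataset, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- tryCatch(as.character(utils::packageVersion("ipssirt")),
                  error = function(e) "dev")
  writeLines(sprintf("# ipssirt %s | %d rows | seed %s", ver, nrow(dataset),
                     if (is.null(seed)) "NA" else seed), con)
  utils::write.csv(as.data.frame(dataset), con, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an item bank as CSV
#'
#' One row per item: `item, dimension, a, tau1..tau5` (absolute
#' thresholds).
#'
#' @param bank a `grm_item_bank`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_item_bank_csv <- function(bank, path) {
  utils::write.csv(bank_to_table(bank), path, row.names = FALSE)
  invisible(path)
}

#' Read an item bank from CSV
#'
#' @param path CSV written by [write_item_bank_csv()] (or the packaged
#'   fixture `system.file("extdata", "ipss_item_bank.csv", package =
#'   "ipssirt")`, which holds the reference unidimensional and
#'   bidimensional parameter sets in a `model` column).
#' @param model when the file carries a `model` column, which set to read.
#' @return A `grm_item_bank`.
#' @export
read_item_bank_csv <- function(path, model = NULL) {
  df <- utils::read.csv(path)
  if (!is.null(df$model) && !is.null(model))
    df <- df[df$model == model, , drop = FALSE]
  ndim <- if (all(df$dimension == "general")) 1L else 2L
  items <- lapply(seq_len(nrow(df)), function(r)
    item_parameters(df$item[r],
                    df$a[r],
                    as.numeric(df[r, grep("^tau", names(df))]),
                    df$dimension[r]))
  item_bank(items, ndim)
}

#' Serialize an ICC fit to YAML
#'
#' @param fit an `icc_fit`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_icc_fit <- function(fit, path) {
  obj <- list(
    n_dimensions = fit$n_dimensions,
    items = lapply(fit$bank$items, function(it)
      list(item = it$item, dimension = it$dimension, a = it$a,
           thresholds = it$thresholds)),
    shift = list(post_mean = fit$shift$post_mean,
                 post_variance = fit$shift$post_variance,
                 correlation = fit$shift$correlation),
    ofv = fit$ofv, aic = fit$aic, n_params = fit$n_params,
    converged = fit$converged, n_pseudo = fit$n_pseudo)
  if (!is.null(fit$se_table))
    obj$se <- stats::setNames(as.list(fit$se_table$se),
                              fit$se_table$parameter)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read an ICC fit from YAML
#'
#' @param path YAML path written by [write_icc_fit()].
#' @return An `icc_fit` (bank, shift and fit statistics; no refitting).
#' @export
read_icc_fit <- function(path) {
  obj <- yaml::read_yaml(path)
  items <- lapply(obj$items, function(it)
    item_parameters(it$item, it$a, unlist(it$thresholds), it$dimension))
  bank <- item_bank(items, obj$n_dimensions)
  shift <- latent_shift(unlist(obj$shift$post_mean),
                        unlist(obj$shift$post_variance),
                        obj$shift$correlation)
  structure(list(bank = bank, shift = shift, ofv = obj$ofv, aic = obj$aic,
                 n_params = obj$n_params, converged = obj$converged,
                 shift_identified = TRUE, n_pseudo = obj$n_pseudo,
                 n_dimensions = obj$n_dimensions, se_table = NULL),
            class = "icc_fit")
}

#' Run the full analysis pipeline
#'
#' Drives the stages end to end on one synthetic trial: simulate,
#' unidimensional (and optionally bidimensional) ICC estimation,
#' disability estimates, information report, PSI-IPPSE longitudinal fit,
#' diagnostics, and (optionally) a scaled power run. Each stage writes its
#' outputs under `out_dir` and is skipped when its output file already
#' exists, so deleting an intermediate regenerates only downstream stages.
#'
#' @param config named list (or path to a YAML file with the same fields):
#'   `out_dir`; `seed`; `n_patients`; `visit_times`; optional toggles
#'   `fit_bidimensional`, `run_power` (both FALSE by default); `power_reps`
#'   and `power_n` for the power stage; `gam_samples` for the diagnostic.
#' @return Invisibly, the list of artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(out_dir = "ipssirt-run", seed = 1L, n_patients = 100L,
         visit_times = c(0, 0.5, 1, 2, 3, 4, 5, 6),
         fit_bidimensional = FALSE, run_power = FALSE,
         power_reps = 20L, power_n = c(33L, 66L), gam_samples = 20L),
    config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  logln <- function(...) cat(sprintf("[%s] ", format(Sys.time(),
                                                     "%H:%M:%S")),
                             sprintf(...), "\n", sep = "",
                             file = log_path, append = TRUE)
  stage <- function(name, path, producer) {
    if (file.exists(path)) {
      logln("%s: reusing %s", name, path)
    } else {
      logln("%s: computing (seed %d)", name, cfg$seed)
      producer(path)
    }
    paths[[name]] <<- path
    path
  }
  truth <- simulation_truth()
  p_data <- stage("simulate", file.path(cfg$out_dir, "trial.csv"),
                  function(p) {
    des <- trial_design(n_patients = cfg$n_patients,
                        visit_times = cfg$visit_times, seed = cfg$seed)
    write_trial_csv(simulate_trial(des, truth), p, seed = cfg$seed)
  })
  dat <- read_trial_csv(p_data)
  p_icc <- stage("fit_icc_uni", file.path(cfg$out_dir, "iccfit_uni.yaml"),
                 function(p) write_icc_fit(fit_icc(dat, 1L, se = FALSE), p))
  fit1 <- read_icc_fit(p_icc)
  if (cfg$fit_bidimensional)
    stage("fit_icc_bi", file.path(cfg$out_dir, "iccfit_bi.yaml"),
          function(p) write_icc_fit(fit_icc(dat, 2L, se = FALSE), p))
  p_ebe <- stage("ebe", file.path(cfg$out_dir, "ebe.csv"), function(p) {
    eb <- disability_estimates(fit1, dat)
    utils::write.csv(as.data.frame(eb), p, row.names = FALSE)
  })
  ebe <- utils::read.csv(p_ebe)
  class(ebe) <- c("ebe_table", "data.frame")
  stage("information", file.path(cfg$out_dir, "information.csv"),
        function(p) {
    rep_ <- information_share(fit1$bank, range(ebe$ebe))
    utils::write.csv(as.data.frame(rep_), p, row.names = FALSE)
  })
  stage("psi_ippse", file.path(cfg$out_dir, "fit_psi_ippse.yaml"),
        function(p) {
    f <- fit_psi_ippse(ebe, dat)
    yaml::write_yaml(list(kind = f$kind, ofv = f$ofv, aic = f$aic,
                          converged = f$converged,
                          params = f$params[!vapply(f$params, is.data.frame,
                                                    TRUE)],
                          iiv_sd = as.list(f$iiv_sd),
                          residual = f$residual), p)
  })
  stage("gam_check", file.path(cfg$out_dir, "gam_check.csv"), function(p) {
    chk <- sampled_gam_icc_check(fit1, ebe, dat,
                                 n_samples = cfg$gam_samples,
                                 seed = cfg$seed)
    utils::write.csv(chk$curves, p, row.names = FALSE)
  })
  stage("rescor", file.path(cfg$out_dir, "residual_correlation.csv"),
        function(p) {
    cm <- residual_correlation(fit1, ebe, dat)
    utils::write.csv(as.data.frame(cm), p, row.names = TRUE)
  })
  if (cfg$run_power)
    stage("power", file.path(cfg$out_dir, "power.csv"), function(p) {
      pw <- sse_power(n_grid = cfg$power_n, n_reps = cfg$power_reps,
                      n_null_reps = cfg$power_reps,
                      methods = c("total", "ancova3m", "ancovawot"),
                      seed = cfg$seed)
      utils::write.csv(as.data.frame(pw), p, row.names = FALSE)
    })
  logln("pipeline complete")
  invisible(paths)
}
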