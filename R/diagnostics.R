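# Model diagnostics: the eta-sampling GAM ICC check (a shrinkage-robust
# extension of the classic EBE-based GAM smooth), residual item
# correlations, and visual predictive checks.

#' Sampling-based GAM check of item characteristic curves
#'
#' For every pseudo-individual, disability values are drawn from the
#' posterior approximation N(EBE, SE^2) implied by the fitted ICC model
#' (the draws respect each pseudo-individual's baseline/post-baseline
#' origin because EBE and SE were computed under that origin's prior).
#' For each item and cumulative score category, a cross-validated cubic
#' spline smooth (generalized cross-validation, basis dimension 10) of the
#' binary exceedance indicator against sampled disability is compared with
#' the model's cumulative probability curve. Because the smooth sees
#' `n_samples` copies of every real observation, its confidence band is
#' widened by multiplying the standard error by `sqrt(n_samples)`.
#'
#' @param fit an `icc_fit`.
#' @param ebe `ebe_table` from [disability_estimates()].
#' @param data the trial dataset or IDVIS table.
#' @param n_samples posterior draws per pseudo-individual (>= 1; 1 with
#'   zero SEs reproduces the traditional EBE-based smooth).
#' @param grid_points evaluation grid size per panel.
#' @param seed integer seed for the posterior draws.
#' @return Object of class `gam_icc_check`: list with `curves` (data.frame
#'   `item, k, psi, smooth, lo, hi, icc`), `panels` (per item-category
#'   fraction of grid points where the model curve leaves the band, and a
#'   flag at > 10%), and `n_samples`.
#' @export
sampled_gam_icc_check <- function(fit, ebe, data, n_samples = 200L,
                                  grid_points = 100L, seed = 1L) {
  if (n_samples < 1L) stop("`n_samples` must be >= 1", call. = FALSE)
  if (any(!is.finite(ebe$se))) stop("EBE standard errors required",
                                    call. = FALSE)
  pseudo <- if (inherits(data, "idvis_table")) data else reshape_idvis(data)
  Y <- score_matrix(pseudo)
  set.seed(seed)
  bank <- fit$bank
  dimof <- bank_dim_index(bank)
  curves <- vector("list", 35L)
  panels <- vector("list", 35L)
  ii <- 0L
  for (d in seq_len(fit$n_dimensions)) {
    e <- ebe[ebe$dim == d, ]
    # draws: n_pseudo x n_samples disability values
    psi_s <- matrix(stats::rnorm(nrow(e) * n_samples, e$ebe, e$se),
                    nrow(e), n_samples)
    grid <- seq(min(psi_s), max(psi_s), length.out = grid_points)
    for (j in which(dimof == d)) {
      y <- Y[, j]
      obs <- which(!is.na(y))
      for (k in 1:5) {
        ii <- ii + 1L
        ind <- as.numeric(y[obs] >= k)
        df <- data.frame(ind = rep(ind, n_samples),
                         psi = as.vector(psi_s[obs, , drop = FALSE]))
        g <- mgcv::gam(ind ~ s(psi, bs = "cr", k = 10), data = df,
                       family = stats::binomial(), method = "GCV.Cp")
        pr <- mgcv::predict.gam(g, data.frame(psi = grid), se.fit = TRUE)
        wid <- 1.96 * pr$se.fit * sqrt(n_samples)
        icc <- cumulative_probability(bank$items[[j]], grid, k)
        cv <- data.frame(item = j, k = k, psi = grid,
                         smooth = stats::plogis(pr$fit),
                         lo = stats::plogis(pr$fit - wid),
                         hi = stats::plogis(pr$fit + wid),
                         icc = icc)
        curves[[ii]] <- cv
        out_frac <- mean(icc < cv$lo | icc > cv$hi)
        panels[[ii]] <- data.frame(item = j, k = k, outside = out_frac,
                                   flagged = out_frac > 0.1)
      }
    }
  }
  structure(list(curves = do.call(rbind, curves),
                 panels = do.call(rbind, panels),
                 n_samples = n_samples),
            class = "gam_icc_check")
}

#' @export
print.gam_icc_check <- function(x, ...) {
  cat(sprintf("Sampling-based GAM ICC check (%d samples): %d/%d panels flagged\n",
              x$n_samples, sum(x$panels$flagged), nrow(x$panels)))
  if (any(x$panels$flagged))
    print(x$panels[x$panels$flagged, ], row.names = FALSE)
  invisible(x)
}

#' Residual correlation between items
#'
#' Residuals are observed score minus the expected score under the fitted
#' ICCs at each pseudo-individual's disability estimate; their pairwise
#' Pearson correlations across pseudo-individuals diagnose violations of
#' local independence (e.g. item pairs sharing an unmodelled dimension).
#'
#' @param fit an `icc_fit`.
#' @param ebe `ebe_table` for the same data.
#' @param data trial dataset or IDVIS table.
#' @return 7x7 correlation matrix (unit diagonal) with the residual matrix
#'   as attribute `"residuals"`.
#' @export
residual_correlation <- function(fit, ebe, data) {
  pseudo <- if (inherits(data, "idvis_table")) data else reshape_idvis(data)
  Y <- score_matrix(pseudo)
  dimof <- bank_dim_index(fit$bank)
  res <- matrix(NA_real_, nrow(Y), 7L)
  for (d in seq_len(fit$n_dimensions)) {
    e <- ebe[ebe$dim == d, ]
    for (j in which(dimof == d))
      res[, j] <- Y[, j] - expected_score(fit$bank$items[[j]], e$ebe)
  }
  v <- apply(res, 2L, stats::var, na.rm = TRUE)
  if (any(v < 1e-12, na.rm = TRUE))
    stop("item with zero residual variance: ",
         paste(which(v < 1e-12), collapse = ", "), call. = FALSE)
  cm <- stats::cor(res, use = "pairwise.complete.obs")
  dimnames(cm) <- list(paste0("item", 1:7), paste0("item", 1:7))
  attr(cm, "residuals") <- res
  cm
}

# Simulate one replicate of the observed design from a fitted model or
# simulation truth. Returns a data.frame with at least patient_id, arm,
# time_months, total (and item columns for item-level models).
simulate_replicate <- function(model, dataset, seed) {
  if (inherits(model, "simulation_truth")) {
    pats <- dataset[!duplicated(dataset$patient_id),
                    c("patient_id", "arm", "dose_mg", "qol_base",
                      "bii_base", "region")]
    lg <- model$longitudinal
    set.seed(seed)
    eta <- draw_etas(nrow(pats), iiv_covariance(lg$iiv, lg$correlations))
    colnames(eta) <- paste0("eta_", colnames(eta))
    pats <- cbind(pats, eta)
    visit_times <- sort(unique(dataset$time_months))
    traj <- generate_trajectories(pats, model, visit_times)
    ndim <- model$bank$n_dimensions
    dimof <- bank_dim_index(model$bank)
    out <- data.frame(patient_id = traj$patient_id,
                      time_months = traj$time_months)
    out$arm <- pats$arm[match(out$patient_id, pats$patient_id)]
    for (j in 1:7)
      out[[paste0("item", j)]] <-
        grm_simulate_item(model$bank$items[[j]],
                          traj[[paste0("psi", dimof[j])]])
    out$total <- rowSums(as.matrix(out[paste0("item", 1:7)]))
    # keep only observed (patient, time) combinations
    keep <- paste(out$patient_id, out$time_months) %in%
      paste(dataset$patient_id, dataset$time_months)
    return(out[keep, , drop = FALSE])
  }
  stopifnot(inherits(model, "long_fit"), model$kind == "total-score")
  set.seed(seed)
  sd_ <- subject_design(dataset)
  p <- model$params
  eta <- cbind(stats::rnorm(sd_$n, 0, model$iiv_sd[["baseline"]]),
               stats::rnorm(sd_$n, 0, model$iiv_sd[["pmax"]]),
               stats::rnorm(sd_$n, 0, model$iiv_sd[["tprog"]]),
               stats::rnorm(sd_$n, 0, model$iiv_sd[["drift"]]))
  eb <- if (!is.null(p$boxcox_baseline))
    boxcox_eta(eta[, 1L], p$boxcox_baseline) else eta[, 1L]
  ed <- if (!is.null(p$boxcox_drift))
    boxcox_eta(eta[, 4L], p$boxcox_drift) else eta[, 4L]
  base_typ <- rep(p$baseline, sd_$n)
  pmax_typ <- rep(p$pmax, sd_$n)
  if (!is.null(p$covariates)) for (r in seq_len(nrow(p$covariates))) {
    cvn <- p$covariates$covariate[r]
    dev <- sd_$data[[cvn]][sd_$first] - model$covariate_centers[[cvn]]
    tgt <- p$covariates$parameter[r]
    if (p$covariates$form[r] == "multiplicative") {
      if (tgt == "baseline") base_typ <- base_typ *
          (1 + p$covariates$coef[r] * dev)
      else pmax_typ <- pmax_typ * (1 + p$covariates$coef[r] * dev)
    } else {
      if (tgt == "baseline") base_typ <- base_typ + p$covariates$coef[r] * dev
      else pmax_typ <- pmax_typ + p$covariates$coef[r] * dev
    }
  }
  base_i <- base_typ * exp(eb)
  pmax_i <- pmax_typ + eta[, 2L]
  tprog_i <- p$tprog * exp(eta[, 3L])
  pred <- base_i[sd_$sub] +
    pmax_i[sd_$sub] * (1 - exp(-log(2) * sd_$t / tprog_i[sd_$sub])) +
    ed[sd_$sub] * sd_$t +
    p$drug * (sd_$active & sd_$post)
  sdv <- sqrt(model$residual$add^2 + (model$residual$prop * pred)^2)
  data.frame(patient_id = sd_$data$patient_id, arm = sd_$data$arm,
             time_months = sd_$t,
             total = pred + stats::rnorm(length(pred), 0, sdv))
}

#' Visual predictive check
#'
#' Simulates replicate trials at the observed design and compares observed
#' 5th/50th/95th percentiles of the dependent variable per nominal visit
#' (and per item for `level = "item"`) with the 95% confidence intervals of
#' the same percentiles across simulations.
#'
#' @param model a `long_fit` of kind `"total-score"` or a
#'   [simulation_truth()] / [as_simulation_truth()] for item-level models.
#' @param dataset observed trial dataset.
#' @param n_sim number of replicate simulations (>= 20; conventional
#'   defaults are 200 for summary-score models and 2000 for item-level
#'   models).
#' @param level `"summary"` (total score) or `"item"`.
#' @param change_from_baseline stratify by arm and use change from baseline.
#' @param seed integer seed.
#' @return Object of class `vpc_result`: data.frame with one row per bin
#'   and percentile: `level, item, time_months, arm, stat, observed, lo,
#'   hi`, plus `coverage` (fraction of median bins covered).
#' @export
vpc <- function(model, dataset, n_sim = 200L,
                level = c("summary", "item"),
                change_from_baseline = FALSE, seed = 1L) {
  level <- match.arg(level)
  if (n_sim < 20L) stop("`n_sim` must be at least 20", call. = FALSE)
  if (level == "item" && !inherits(model, "simulation_truth"))
    stop("item-level VPC needs an item-level simulation model",
         call. = FALSE)
  probs <- c(0.05, 0.5, 0.95)
  dv_frame <- function(d) {
    if (change_from_baseline) {
      b <- d$total[match(paste(d$patient_id, 0),
                         paste(d$patient_id, d$time_months))]
      d$dv <- d$total - b
      d$grp <- ifelse(tolower(d$arm) == "placebo", "placebo", "active")
    } else {
      d$dv <- d$total
      d$grp <- "all"
    }
    d
  }
  obs_stats <- function(d) {
    d <- dv_frame(d)
    if (level == "summary") {
      out <- do.call(rbind, lapply(split(d, list(d$time_months, d$grp),
                                         drop = TRUE), function(s)
        data.frame(item = NA_integer_, time_months = s$time_months[1L],
                   arm = s$grp[1L], stat = paste0("p", probs * 100),
                   value = unname(stats::quantile(s$dv, probs,
                                                  na.rm = TRUE)))))
    } else {
      out <- do.call(rbind, lapply(1:7, function(j)
        do.call(rbind, lapply(split(d, d$time_months), function(s)
          data.frame(item = j, time_months = s$time_months[1L], arm = "all",
                     stat = paste0("p", probs * 100),
                     value = unname(stats::quantile(s[[paste0("item", j)]],
                                                    probs, na.rm = TRUE)))))))
    }
    rownames(out) <- NULL
    out
  }
  obs <- obs_stats(dataset)
  sims <- matrix(NA_real_, nrow(obs), n_sim)
  for (r in seq_len(n_sim)) {
    rep_dat <- simulate_replicate(model, dataset, seed = seed * 100000L + r)
    sims[, r] <- obs_stats(rep_dat)$value
  }
  out <- obs
  names(out)[names(out) == "value"] <- "observed"
  out$lo <- apply(sims, 1L, stats::quantile, 0.025)
  out$hi <- apply(sims, 1L, stats::quantile, 0.975)
  med <- out$stat == "p50"
  structure(list(table = out, n_sim = n_sim, level = level,
                 coverage = mean(out$observed[med] >= out$lo[med] &
                                   out$observed[med] <= out$hi[med])),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC (%s level, %d simulations): median coverage %.0f%% of bins\n",
              x$level, x$n_sim, 100 * x$coverage))
  invisible(x)
}
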