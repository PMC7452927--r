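# Longitudinal mixed-effects fits: the total-IPSS model, the sequential
# PSI-IPPSE latent-disability model (EBE standard errors entering as a
# known additive residual component), and the joint item-level model with
# fixed or re-estimated ICCs. All marginalize subject random effects by
# per-subject Laplace approximation (vectorized across subjects).

# covariate specification rows: data.frame(parameter, covariate, form)
validate_covariates <- function(covariates, data) {
  if (is.null(covariates) || !nrow(covariates)) return(NULL)
  keep <- logical(nrow(covariates))
  for (r in seq_len(nrow(covariates))) {
    v <- data[[covariates$covariate[r]]]
    if (is.null(v)) stop("covariate ", covariates$covariate[r],
                         " not in data", call. = FALSE)
    if (length(unique(v[!is.na(v)])) < 2L) {
      warning("constant covariate ", covariates$covariate[r], " skipped",
              call. = FALSE)
    } else keep[r] <- TRUE
  }
  covariates[keep, , drop = FALSE]
}

# Per-subject design: order rows by subject, extract times/arms/covariates.
subject_design <- function(data) {
  data <- data[order(data$patient_id, data$time_months), , drop = FALSE]
  ids <- unique(data$patient_id)
  sub <- match(data$patient_id, ids)
  first <- !duplicated(data$patient_id)
  ends <- c(which(diff(sub) > 0L), length(sub))
  list(data = data, ids = ids, sub = sub, n = length(ids),
       t = data$time_months, active = data$dose_mg > 0,
       post = data$time_months > 0, first = first, ends = ends)
}

# Per-subject sums of a row vector (rows sorted by subject).
seg_sums <- function(x, ends) {
  cs <- cumsum(x)
  cs[ends] - c(0, cs[ends[-length(ends)]])
}

# Gaussian log-density without dnorm's dispatch overhead.
fast_dnorm_log <- function(y, mu, sd) {
  -0.5 * ((y - mu) / sd)^2 - log(sd) - 0.9189385332046727
}

# Apply covariate effects to a per-subject typical-value vector.
apply_covariates <- function(val, par, covariates, centers, sd_data, first) {
  if (is.null(covariates)) return(val)
  for (r in which(covariates$parameter == par)) {
    cv <- covariates$covariate[r]
    dev <- sd_data[[cv]][first] - centers[[cv]]
    if (covariates$form[r] == "multiplicative")
      val <- val * (1 + covariates$coef[r] * dev)
    else val <- val + covariates$coef[r] * dev
  }
  val
}

long_fit_object <- function(kind, res, names_theta, natural, iiv_sd, extra) {
  out <- c(list(kind = kind, ofv = res$ofv, converged = res$converged,
                message = res$message,
                theta_trans = stats::setNames(res$theta, names_theta),
                params = natural, iiv_sd = iiv_sd, eta = res$eta,
                neg2ll = res$neg2ll), extra)
  out$aic <- res$ofv + 2 * length(res$theta)
  class(out) <- "long_fit"
  out
}

#' @export
print.long_fit <- function(x, ...) {
  cat(sprintf("Longitudinal %s model: %d subjects, OFV = %.2f (%s)\n",
              x$kind, x$n_subjects, x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  p <- x$params[!vapply(x$params, is.data.frame, logical(1L))]
  print(signif(unlist(p), 4))
  if (!is.null(x$params$covariates)) {
    cat("Covariates:\n"); print(x$params$covariates, row.names = FALSE)
  }
  cat("IIV SD:", paste(names(x$iiv_sd), signif(x$iiv_sd, 3), sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}

#' Fit the longitudinal total-IPSS model
#'
#' Nonlinear mixed-effects model for observed total scores:
#' `total = baseline * exp(eta_B) + (pmax + eta_P)(1 - exp(-ln 2 t /
#' tprog_i)) + eta_D t + drug` with log-normal inter-individual variability
#' on baseline and placebo half-life, normal variability on maximal placebo
#' response and drift (typical drift fixed at zero), an offset drug effect
#' on active arms, and combined proportional + additive residual error.
#' Marginalization is by per-subject Laplace approximation.
#'
#' @param dataset long-format data with `patient_id, arm, dose_mg,
#'   time_months, total` and any covariate columns.
#' @param drug_effect estimate the offset drug effect (full model) or fix
#'   it to zero (reduced model).
#' @param covariates optional data.frame `parameter, covariate, form`
#'   (forms `"multiplicative"`/`"additive"`, centered at sample medians).
#' @param boxcox character vector among `c("baseline", "drift")`: estimate a
#'   Box-Cox shape for these random-effect distributions.
#' @param se compute standard errors (finite-difference Hessian).
#' @param control list passed to the Laplace engine (`outer_iter`,
#'   `inner_iter`, ...).
#' @return A `long_fit` with elements `params` (natural-scale fixed
#'   effects), `iiv_sd`, `residual`, `ofv`, `aic`, `converged`.
#' @export
fit_total_score <- function(dataset, drug_effect = TRUE, covariates = NULL,
                            boxcox = NULL, start = NULL, se = FALSE,
                            control = list()) {
  dataset <- dataset[!is.na(dataset$total), , drop = FALSE]
  sd_ <- subject_design(dataset)
  covariates <- validate_covariates(covariates, sd_$data)
  centers <- lapply(stats::setNames(nm = unique(covariates$covariate)),
                    function(cv) stats::median(sd_$data[[cv]], na.rm = TRUE))
  y <- sd_$data$total
  bc_base <- "baseline" %in% boxcox
  bc_drift <- "drift" %in% boxcox
  nm <- c("log_baseline", "pmax", "log_tprog",
          if (drug_effect) "drug",
          if (!is.null(covariates))
            paste0("cov_", covariates$parameter, "_", covariates$covariate),
          if (bc_base) "log_bc_baseline", if (bc_drift) "log_bc_drift",
          "log_om_baseline", "log_om_pmax", "log_om_tprog", "log_om_drift",
          "log_sd_prop", "log_sd_add")
  ncov <- if (is.null(covariates)) 0L else nrow(covariates)
  idx <- function(s) which(nm == s)
  cll <- function(theta, eta) {
    cv <- covariates
    if (ncov) cv$coef <- theta[3L + (if (drug_effect) 1L else 0L) +
                                 seq_len(ncov)]
    base_typ <- apply_covariates(rep(exp(theta[1L]), sd_$n), "baseline",
                                 cv, centers, sd_$data, sd_$first)
    pmax_typ <- apply_covariates(rep(theta[2L], sd_$n), "pmax",
                                 cv, centers, sd_$data, sd_$first)
    eb <- if (bc_base) boxcox_eta(eta[, 1L], exp(theta[idx("log_bc_baseline")]))
          else eta[, 1L]
    ed <- if (bc_drift) boxcox_eta(eta[, 4L], exp(theta[idx("log_bc_drift")]))
          else eta[, 4L]
    base_i <- base_typ * exp(eb)
    pmax_i <- pmax_typ + eta[, 2L]
    tprog_i <- exp(theta[3L] + eta[, 3L])
    drift_i <- ed
    drug <- if (drug_effect) theta[idx("drug")] else 0
    pred <- base_i[sd_$sub] +
      pmax_i[sd_$sub] * (1 - exp(-log(2) * sd_$t / tprog_i[sd_$sub])) +
      drift_i[sd_$sub] * sd_$t + drug * (sd_$active & sd_$post)
    sdv <- sqrt(exp(2 * theta[idx("log_sd_add")]) +
                  (exp(theta[idx("log_sd_prop")]) * pred)^2)
    seg_sums(fast_dnorm_log(y, pred, sdv), sd_$ends)
  }
  omega_fn <- function(theta) {
    diag(exp(2 * theta[c(idx("log_om_baseline"), idx("log_om_pmax"),
                         idx("log_om_tprog"), idx("log_om_drift"))]),
         nrow = 4L)
  }
  # data-driven starts: placebo-arm mean change sets the placebo scale;
  # an earlier fit (e.g. the reduced model of a full/reduced pair) can be
  # passed to warm-start everything else
  base0 <- max(mean(y[!sd_$post]), 1)
  plc <- !sd_$active
  last_t <- max(sd_$t)
  chg_plc <- mean(y[plc & sd_$t == last_t]) - mean(y[plc & !sd_$post])
  pmax0 <- min(1.5 * chg_plc, -0.5)
  drug0 <- if (drug_effect)
    (mean(y[sd_$active & sd_$post]) - mean(y[sd_$active & !sd_$post])) -
    (mean(y[plc & sd_$post]) - mean(y[plc & !sd_$post])) else NULL
  sv <- if (inherits(start, "long_fit"))
    c(list(baseline = start$params$baseline, pmax = start$params$pmax,
           tprog = start$params$tprog, drug = start$params$drug,
           sd_prop = start$residual$prop, sd_add = start$residual$add),
      as.list(stats::setNames(start$iiv_sd,
                              paste0("om_", names(start$iiv_sd)))))
  else if (is.list(start)) start else list()
  gv <- function(nm_, default) if (is.null(sv[[nm_]])) default else sv[[nm_]]
  start <- c(log(gv("baseline", base0)), gv("pmax", pmax0),
             log(gv("tprog", 0.6 * last_t)),
             if (drug_effect) gv("drug", min(drug0, 0)), rep(0, ncov),
             if (bc_base) log(1), if (bc_drift) log(1),
             log(max(gv("om_baseline", 0.15), 2e-3)),
             log(max(gv("om_pmax", 1.5), 2e-3)),
             log(max(gv("om_tprog", 0.5), 2e-3)),
             log(max(gv("om_drift", 0.1), 2e-3)),
             log(max(gv("sd_prop", 0.1), 2e-3)),
             log(max(gv("sd_add", 1), 2e-3)))
  lower <- rep(-Inf, length(nm)); upper <- rep(Inf, length(nm))
  lower[grep("^log_om|^log_sd", nm)] <- log(1e-3)
  upper[grep("^log_om|^log_sd", nm)] <- log(50)
  lower[grep("^log_bc", nm)] <- log(0.01)
  upper[grep("^log_bc", nm)] <- log(100)
  res <- laplace_nlme(start, cll, omega_fn, sd_$n, 4L,
                      lower = lower, upper = upper, control = control)
  th <- res$theta
  natural <- list(baseline = exp(th[1L]), pmax = th[2L],
                  tprog = exp(th[3L]),
                  drug = if (drug_effect) th[idx("drug")] else 0)
  if (ncov) natural$covariates <- data.frame(
    covariates[c("parameter", "covariate", "form")],
    coef = th[3L + (if (drug_effect) 1L else 0L) + seq_len(ncov)])
  if (bc_base) natural$boxcox_baseline <- exp(th[idx("log_bc_baseline")])
  if (bc_drift) natural$boxcox_drift <- exp(th[idx("log_bc_drift")])
  iiv_sd <- exp(th[c(idx("log_om_baseline"), idx("log_om_pmax"),
                     idx("log_om_tprog"), idx("log_om_drift"))])
  names(iiv_sd) <- c("baseline", "pmax", "tprog", "drift")
  at_bound <- iiv_sd <= 1.05e-3
  fit <- long_fit_object("total-score", res, nm, natural, iiv_sd,
    list(residual = list(prop = exp(th[idx("log_sd_prop")]),
                         add = exp(th[idx("log_sd_add")])),
         n_subjects = sd_$n, drug_effect = drug_effect,
         iiv_at_bound = names(iiv_sd)[at_bound],
         covariate_centers = centers, data_order = sd_$ids))
  if (any(at_bound))
    fit$converged_notes <- paste("IIV variance at lower bound:",
                                 paste(names(iiv_sd)[at_bound],
                                       collapse = ", "))
  if (se) fit <- add_long_se(fit)
  fit
}

#' Fit the sequential PSI-IPPSE latent-disability model
#'
#' Models per patient-visit MAP disability estimates longitudinally with
#' the same structural model as [fit_total_score()] (additive covariates,
#' normal IIV on baseline, maximal placebo response and drift, log-normal
#' on the placebo half-life). Each observation's known estimation standard
#' error enters the residual variance as `se^2 + sd_add^2`, with only
#' `sd_add` estimated — the latent analogue of the IPPSE approach to
#' sequential modelling with individual-parameter standard errors.
#'
#' @param ebe an `ebe_table` from [disability_estimates()] (unidimensional).
#' @param dataset the trial dataset (supplies arm, dose and covariates).
#' @inheritParams fit_total_score
#' @return A `long_fit`.
#' @export
fit_psi_ippse <- function(ebe, dataset, drug_effect = TRUE, covariates = NULL,
                          start = NULL, se = FALSE, control = list()) {
  if (is.null(ebe$se) || any(!is.finite(ebe$se)))
    stop("EBE standard errors are required by the PSI-IPPSE approach",
         call. = FALSE)
  if (any(ebe$dim != 1L))
    ebe <- ebe[ebe$dim == 1L, , drop = FALSE]
  key <- paste(dataset$patient_id, dataset$time_months)
  m <- match(paste(ebe$patient_id, ebe$time_months), key)
  dat <- data.frame(patient_id = ebe$patient_id,
                    time_months = ebe$time_months,
                    y = ebe$ebe, se_obs = ebe$se,
                    dose_mg = dataset$dose_mg[m],
                    arm = dataset$arm[m])
  for (cv in unique(covariates$covariate))
    dat[[cv]] <- dataset[[cv]][m]
  sd_ <- subject_design(dat)
  covariates <- validate_covariates(covariates, sd_$data)
  centers <- lapply(stats::setNames(nm = unique(covariates$covariate)),
                    function(cv) stats::median(sd_$data[[cv]], na.rm = TRUE))
  y <- sd_$data$y
  se2 <- sd_$data$se_obs^2
  ncov <- if (is.null(covariates)) 0L else nrow(covariates)
  nm <- c("baseline", "pmax", "log_tprog", if (drug_effect) "drug",
          if (ncov) paste0("cov_", covariates$parameter, "_",
                           covariates$covariate),
          "log_om_baseline", "log_om_pmax", "log_om_tprog", "log_om_drift",
          "log_sd_add")
  idx <- function(s) which(nm == s)
  cll <- function(theta, eta) {
    cv <- covariates
    if (ncov) cv$coef <- theta[3L + (if (drug_effect) 1L else 0L) +
                                 seq_len(ncov)]
    base_i <- apply_covariates(rep(theta[1L], sd_$n), "baseline", cv,
                               centers, sd_$data, sd_$first) + eta[, 1L]
    pmax_i <- apply_covariates(rep(theta[2L], sd_$n), "pmax", cv,
                               centers, sd_$data, sd_$first) + eta[, 2L]
    tprog_i <- exp(theta[3L] + eta[, 3L])
    drift_i <- eta[, 4L]
    drug <- if (drug_effect) theta[idx("drug")] else 0
    pred <- base_i[sd_$sub] +
      pmax_i[sd_$sub] * (1 - exp(-log(2) * sd_$t / tprog_i[sd_$sub])) +
      drift_i[sd_$sub] * sd_$t + drug * (sd_$active & sd_$post)
    sdv <- sqrt(se2 + exp(2 * theta[idx("log_sd_add")]))
    seg_sums(fast_dnorm_log(y, pred, sdv), sd_$ends)
  }
  omega_fn <- function(theta)
    diag(exp(2 * theta[c(idx("log_om_baseline"), idx("log_om_pmax"),
                         idx("log_om_tprog"), idx("log_om_drift"))]),
         nrow = 4L)
  sv <- if (inherits(start, "long_fit"))
    c(list(baseline = start$params$baseline, pmax = start$params$pmax,
           tprog = start$params$tprog, drug = start$params$drug,
           sd_add = start$residual$add),
      as.list(stats::setNames(start$iiv_sd,
                              paste0("om_", names(start$iiv_sd)))))
  else if (is.list(start)) start else list()
  if (inherits(start, "long_fit") && ncov &&
      !is.null(start$params$covariates)) {
    # carry over coefficients of covariates shared with the starting fit
    sc <- start$params$covariates
    sv$cov <- vapply(seq_len(ncov), function(r) {
      m <- which(sc$parameter == covariates$parameter[r] &
                   sc$covariate == covariates$covariate[r])
      if (length(m)) sc$coef[m[1L]] else 0
    }, numeric(1L))
  }
  gv <- function(nm_, default) if (is.null(sv[[nm_]])) default else sv[[nm_]]
  start <- c(gv("baseline", mean(y[!sd_$post])), gv("pmax", -0.5),
             log(gv("tprog", 3)), if (drug_effect) gv("drug", -0.2),
             if (ncov) gv("cov", rep(0, ncov)),
             log(max(gv("om_baseline", 0.7), 2e-3)),
             log(max(gv("om_pmax", 1), 2e-3)),
             log(max(gv("om_tprog", 0.5), 2e-3)),
             log(max(gv("om_drift", 0.05), 2e-3)),
             log(max(gv("sd_add", 0.2), 2e-3)))
  lower <- rep(-Inf, length(nm)); upper <- rep(Inf, length(nm))
  lower[grep("^log_om|^log_sd", nm)] <- log(1e-3)
  upper[grep("^log_om|^log_sd", nm)] <- log(20)
  res <- laplace_nlme(start, cll, omega_fn, sd_$n, 4L, lower = lower,
                      upper = upper, control = control)
  th <- res$theta
  natural <- list(baseline = th[1L], pmax = th[2L], tprog = exp(th[3L]),
                  drug = if (drug_effect) th[idx("drug")] else 0)
  if (ncov) natural$covariates <- data.frame(
    covariates[c("parameter", "covariate", "form")],
    coef = th[3L + (if (drug_effect) 1L else 0L) + seq_len(ncov)])
  iiv_sd <- exp(th[c(idx("log_om_baseline"), idx("log_om_pmax"),
                     idx("log_om_tprog"), idx("log_om_drift"))])
  names(iiv_sd) <- c("baseline", "pmax", "tprog", "drift")
  fit <- long_fit_object("psi-ippse", res, nm, natural, iiv_sd,
    list(residual = list(add = exp(th[idx("log_sd_add")])),
         n_subjects = sd_$n, drug_effect = drug_effect,
         covariate_centers = centers, data_order = sd_$ids))
  if (se) fit <- add_long_se(fit)
  fit
}

#' Fit the joint item-level longitudinal IRT model
#'
#' Combines the graded-response measurement model with the longitudinal
#' latent-disability structural model in a single likelihood: each
#' patient's latent disability follows baseline + placebo + drug with
#' subject random effects, and the observed item scores enter through the
#' graded-response category probabilities. Random effects are marginalized
#' per patient by Laplace approximation. With `re_estimate_icc = FALSE`
#' (the default, and the final-model choice) the ICCs stay fixed at the
#' supplied bank; with `TRUE` the 42 item parameters are re-estimated
#' jointly with the longitudinal parameters.
#'
#' @param dataset long-format item-level trial data.
#' @param bank `grm_item_bank` from the ICC estimation stage.
#' @param re_estimate_icc re-estimate item parameters jointly.
#' @param estimate_wei estimate a Weibull shape for the placebo model
#'   (default for bidimensional banks, where it is shared across
#'   dimensions).
#' @param start optional warm start: a `long_fit` from [fit_psi_ippse()]
#'   (unidimensional) or a named list of natural-scale values among
#'   `baseline(_v/_s), pmax(_v/_s), tprog(_v/_s), drug(_v/_s), wei` and
#'   IIV SDs `om_*`.
#' @inheritParams fit_total_score
#' @return A `long_fit`.
#' @export
fit_joint <- function(dataset, bank, re_estimate_icc = FALSE,
                      drug_effect = TRUE, covariates = NULL,
                      estimate_wei = bank$n_dimensions == 2L,
                      start = NULL, se = FALSE, control = list()) {
  sd_ <- subject_design(dataset)
  covariates <- validate_covariates(covariates, sd_$data)
  centers <- lapply(stats::setNames(nm = unique(covariates$covariate)),
                    function(cv) stats::median(sd_$data[[cv]], na.rm = TRUE))
  Y <- score_matrix(sd_$data)
  ndim <- bank$n_dimensions
  dimof <- bank_dim_index(bank)
  ncov <- if (is.null(covariates)) 0L else nrow(covariates)
  if (ndim == 1L) {
    nm <- c("baseline", "pmax", "log_tprog", if (drug_effect) "drug",
            if (estimate_wei) "log_wei",
            if (ncov) paste0("cov_", covariates$parameter, "_",
                             covariates$covariate),
            "log_om_baseline", "log_om_pmax", "log_om_tprog", "log_om_drift")
    k <- 4L
  } else {
    nm <- c("baseline_v", "baseline_s", "pmax_v", "pmax_s",
            "log_tprog_v", "log_tprog_s",
            if (drug_effect) c("drug_v", "drug_s"),
            if (estimate_wei) "log_wei",
            if (ncov) paste0("cov_", covariates$parameter, "_",
                             covariates$covariate),
            "log_om_baseline_v", "log_om_baseline_s", "log_om_pmax",
            "log_om_tprog", "log_om_drift")
    k <- 5L
  }
  n_icc <- 0L
  if (re_estimate_icc) {
    icc_nm <- as.vector(vapply(1:7, function(j)
      paste0("it", j, c("_loga", "_tau1", paste0("_loginc", 2:5))),
      character(6L)))
    nm <- c(nm, icc_nm)
    n_icc <- 42L
  }
  idx <- function(s) which(nm == s)
  z0_icc <- unlist(lapply(bank$items, item_to_trans))
  bank_from_theta <- function(theta) {
    if (!re_estimate_icc) return(bank)
    z <- theta[(length(theta) - 41L):length(theta)]
    items <- lapply(1:7, function(j)
      trans_to_item(z[(j - 1L) * 6L + 1:6], bank$items[[j]]))
    item_bank(items, ndim)
  }
  item_ll_rows <- function(bk, psi_rows) {
    # psi_rows: nrow x ndim latent values; returns per-row item loglik sum
    ll <- numeric(nrow(psi_rows))
    for (j in 1:7) {
      y <- Y[, j]
      obs <- which(!is.na(y))
      if (!length(obs)) next
      p <- category_probabilities(bk$items[[j]], psi_rows[obs, dimof[j]])
      ll[obs] <- ll[obs] + log(pmax(p[cbind(seq_along(obs), y[obs] + 1L)],
                                    .PROB_FLOOR))
    }
    ll
  }
  cll <- function(theta, eta) {
    bk <- bank_from_theta(theta)
    wei <- if (estimate_wei) exp(theta[idx("log_wei")]) else 1
    cv <- covariates
    if (ncov) {
      i0 <- max(grep("^cov_", nm))
      cv$coef <- theta[(i0 - ncov + 1L):i0]
    }
    psi <- matrix(0, nrow(Y), ndim)
    for (d in seq_len(ndim)) {
      sfx <- if (ndim == 1L) "" else if (d == 1L) "_v" else "_s"
      base_i <- apply_covariates(rep(theta[idx(paste0("baseline", sfx))],
                                     sd_$n), paste0("baseline", sfx), cv,
                                 centers, sd_$data, sd_$first) +
        eta[, if (ndim == 1L) 1L else d]
      pmax_i <- theta[idx(paste0("pmax", sfx))] +
        eta[, if (ndim == 1L) 2L else 3L]
      tprog_i <- exp(theta[idx(paste0("log_tprog", sfx))] +
                       eta[, if (ndim == 1L) 3L else 4L])
      drift_i <- eta[, if (ndim == 1L) 4L else 5L]
      drug <- if (drug_effect) theta[idx(paste0("drug", sfx))] else 0
      psi[, d] <- base_i[sd_$sub] +
        pmax_i[sd_$sub] *
          (1 - exp(-(log(2) * sd_$t / tprog_i[sd_$sub])^wei)) +
        drift_i[sd_$sub] * sd_$t + drug * (sd_$active & sd_$post)
    }
    seg_sums(item_ll_rows(bk, psi), sd_$ends)
  }
  om_names <- nm[grep("^log_om", nm)]
  omega_fn <- function(theta)
    diag(exp(2 * theta[match(om_names, nm)]), nrow = k)
  sv <- NULL
  if (inherits(start, "long_fit")) {
    p <- start$params
    sv <- list(baseline = p$baseline, pmax = p$pmax, tprog = p$tprog,
               drug = p$drug)
    for (s in names(start$iiv_sd))
      sv[[paste0("om_", s)]] <- start$iiv_sd[[s]]
    if (!is.null(p$covariates) && ncov &&
        nrow(p$covariates) == ncov) sv$cov <- p$covariates$coef
  } else if (is.list(start)) sv <- start
  gv <- function(nm_, default) {
    v <- sv[[nm_]]
    if (is.null(v)) default else v
  }
  start <- if (ndim == 1L)
    c(gv("baseline", 0), gv("pmax", -0.5), log(gv("tprog", 3)),
      if (drug_effect) gv("drug", -0.2), if (estimate_wei) 0,
      if (ncov) gv("cov", rep(0, ncov)),
      log(gv("om_baseline", 0.8)), log(gv("om_pmax", 1)),
      log(gv("om_tprog", 0.5)), log(max(gv("om_drift", 0.05), 2e-3)))
  else
    c(gv("baseline_v", 0), gv("baseline_s", 0),
      gv("pmax_v", -0.5), gv("pmax_s", -0.5),
      log(gv("tprog_v", 3)), log(gv("tprog_s", 3)),
      if (drug_effect) c(gv("drug_v", -0.2), gv("drug_s", -0.2)),
      if (estimate_wei) log(gv("wei", 1)),
      if (ncov) gv("cov", rep(0, ncov)),
      log(gv("om_baseline_v", 0.9)), log(gv("om_baseline_s", 1.1)),
      log(gv("om_pmax", 1.2)), log(gv("om_tprog", 0.5)),
      log(max(gv("om_drift", 0.05), 2e-3)))
  if (re_estimate_icc) start <- c(start, z0_icc)
  lower <- rep(-Inf, length(nm)); upper <- rep(Inf, length(nm))
  lower[grep("^log_om", nm)] <- log(1e-3)
  upper[grep("^log_om", nm)] <- log(20)
  res <- laplace_nlme(start, cll, omega_fn, sd_$n, k, lower = lower,
                      upper = upper, control = control)
  th <- res$theta
  natural <- as.list(th[seq_len(length(nm) - length(om_names) - n_icc)])
  names(natural) <- nm[seq_along(natural)]
  for (s in grep("^log_", names(natural), value = TRUE)) {
    natural[[sub("^log_", "", s)]] <- exp(natural[[s]])
    natural[[s]] <- NULL
  }
  if (!drug_effect) natural$drug <- 0
  iiv_sd <- exp(th[match(om_names, nm)])
  names(iiv_sd) <- sub("log_om_", "", om_names)
  fit <- long_fit_object("joint-irt", res, nm, natural, iiv_sd,
    list(n_subjects = sd_$n, drug_effect = drug_effect,
         bank = bank_from_theta(th), n_dimensions = ndim,
         re_estimate_icc = re_estimate_icc, estimate_wei = estimate_wei,
         covariate_centers = centers, data_order = sd_$ids))
  if (se) fit <- add_long_se(fit)
  fit
}

# Standard errors for a long_fit via the FD Hessian of -2 loglik.
add_long_se <- function(fit) {
  V <- laplace_vcov(list(theta = unname(fit$theta_trans),
                         neg2ll = fit$neg2ll))
  fit$vcov_trans <- V
  fit$se_trans <- stats::setNames(sqrt(pmax(diag(V), 0)),
                                  names(fit$theta_trans))
  fit
}

#' Stepwise covariate search
#'
#' Greedy forward inclusion / backward elimination on the objective
#' function value: at each forward step the candidate with the largest
#' significant OFV drop (chi-squared, df = 1, p < `forward_p`) enters; the
#' backward pass removes covariates whose OFV contribution fails
#' p < `backward_p`.
#'
#' @param fit_fn function(covariates_df) returning a `long_fit`; the
#'   data and base model options are bound into the closure. If it accepts
#'   a `start` argument, every candidate fit is warm-started from the
#'   current base fit (new coefficients start at zero), which guarantees a
#'   nonnegative OFV drop for nested candidates.
#' @param candidates data.frame `parameter, covariate, form` of candidate
#'   effects.
#' @param forward_p,backward_p significance levels (defaults 0.01 / 0.001).
#' @return list with the final `fit`, the selected `covariates` and a
#'   `trace` data.frame (step, candidate, dOFV, decision).
#' @export
covariate_search <- function(fit_fn, candidates, forward_p = 0.01,
                             backward_p = 0.001) {
  crit_f <- stats::qchisq(1 - forward_p, 1L)
  crit_b <- stats::qchisq(1 - backward_p, 1L)
  selected <- candidates[0, , drop = FALSE]
  warmable <- "start" %in% names(formals(fit_fn))
  fit1 <- function(covs, from)
    if (warmable) fit_fn(covs, start = from) else fit_fn(covs)
  base_fit <- fit_fn(NULL)
  trace <- data.frame(step = character(), candidate = character(),
                      dOFV = numeric(), decision = character())
  note <- function(step, cand, d, dec)
    trace <<- rbind(trace, data.frame(step = step, candidate = cand,
                                      dOFV = d, decision = dec))
  if (!is.null(candidates) && nrow(candidates)) repeat {
    remaining <- candidates[!paste(candidates$parameter,
                                   candidates$covariate) %in%
                              paste(selected$parameter, selected$covariate),
                            , drop = FALSE]
    if (!nrow(remaining)) break
    best <- NULL; best_d <- -Inf; best_fit <- NULL
    for (r in seq_len(nrow(remaining))) {
      cand <- rbind(selected, remaining[r, ])
      f <- try(fit1(cand, base_fit), silent = TRUE)
      if (inherits(f, "try-error")) next
      d <- base_fit$ofv - f$ofv
      note("forward", paste(remaining$parameter[r], remaining$covariate[r],
                            sep = ":"), d, "tested")
      if (d > best_d) { best_d <- d; best <- remaining[r, ]; best_fit <- f }
    }
    if (is.null(best) || best_d < crit_f) break
    selected <- rbind(selected, best)
    base_fit <- best_fit
    note("forward", paste(best$parameter, best$covariate, sep = ":"),
         best_d, "included")
  }
  if (nrow(selected)) repeat {
    worst <- NULL; worst_d <- Inf
    for (r in seq_len(nrow(selected))) {
      cand <- selected[-r, , drop = FALSE]
      f <- fit1(if (nrow(cand)) cand else NULL, base_fit)
      d <- f$ofv - base_fit$ofv       # OFV increase when removed
      note("backward", paste(selected$parameter[r], selected$covariate[r],
                             sep = ":"), d, "tested")
      if (d < worst_d) { worst_d <- d; worst <- r; worst_fit <- f }
    }
    if (worst_d > crit_b) break
    note("backward", paste(selected$parameter[worst],
                           selected$covariate[worst], sep = ":"),
         worst_d, "removed")
    selected <- selected[-worst, , drop = FALSE]
    base_fit <- worst_fit
    if (!nrow(selected)) break
  }
  list(fit = base_fit, covariates = selected, trace = trace)
}

#' Build a simulation truth from a fitted joint model
#'
#' Maps a `long_fit` from [fit_joint()] (plus its item bank) back onto the
#' simulator's truth format so that replicate trials can be simulated from
#' the fitted model (visual predictive checks, power calculations).
#'
#' @param fit a `long_fit` of kind `"joint-irt"`.
#' @param drug override the fitted drug effect(s) (e.g. 0 for null
#'   simulations); scalar or per-dimension vector.
#' @return A [simulation_truth()].
#' @export
as_simulation_truth <- function(fit, drug = NULL) {
  stopifnot(inherits(fit, "long_fit"), fit$kind == "joint-irt")
  p <- fit$params
  ndim <- fit$n_dimensions
  wei <- if (!is.null(p$wei)) p$wei else 1
  if (ndim == 1L) {
    th <- c(baseline = p$baseline, pmax = p$pmax, tprog = p$tprog,
            wei = wei, drift = 0,
            drug = if (is.null(drug)) p$drug else drug[1L])
    iiv <- list(
      baseline = list(dist = "normal", sd = fit$iiv_sd[["baseline"]]),
      pmax = list(dist = "normal", sd = fit$iiv_sd[["pmax"]]),
      tprog = list(dist = "lognormal", sd = fit$iiv_sd[["tprog"]]),
      drift = list(dist = "normal", sd = fit$iiv_sd[["drift"]]))
  } else {
    drug <- if (is.null(drug)) c(p$drug_v, p$drug_s) else rep(drug, 2L)[1:2]
    th <- c(baseline_v = p$baseline_v, baseline_s = p$baseline_s,
            pmax_v = p$pmax_v, pmax_s = p$pmax_s,
            tprog_v = p$tprog_v, tprog_s = p$tprog_s, wei = wei, drift = 0,
            drug_v = drug[1L], drug_s = drug[2L])
    iiv <- list(
      baseline_v = list(dist = "normal", sd = fit$iiv_sd[["baseline_v"]]),
      baseline_s = list(dist = "normal", sd = fit$iiv_sd[["baseline_s"]]),
      pmax = list(dist = "normal", sd = fit$iiv_sd[["pmax"]]),
      tprog = list(dist = "lognormal", sd = fit$iiv_sd[["tprog"]]),
      drift = list(dist = "normal", sd = fit$iiv_sd[["drift"]]))
  }
  simulation_truth(bank = fit$bank,
                   longitudinal = list(theta = th, iiv = iiv,
                                       correlations = NULL,
                                       residual = list(prop = 0, add = 0),
                                       covariates = NULL))
}
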