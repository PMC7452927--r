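# Stochastic simulation and estimation (SSE) power analysis with empirical
# type-I-error calibration, benchmarked against cross-sectional and
# while-on-treatment ANCOVA. Item-level trials are simulated from a
# longitudinal IRT truth (the bidimensional model by default, which had
# the lowest AIC); each replicate is analyzed by likelihood-ratio tests of
# the drug effect in the model-based methods and by ANCOVA p-values, with
# the model LRT thresholds taken from the empirical null distribution of
# the OFV difference rather than the nominal chi-squared cutoff.

#' Cross-sectional ANCOVA at the landmark visit
#'
#' Linear model of the change from baseline in total score at the landmark
#' time on treatment plus baseline total.
#'
#' @param dataset trial dataset with totals at baseline and the landmark.
#' @param landmark landmark time (months, default 3).
#' @param factor `"pooled"` (active vs placebo, t-test on the pooled
#'   indicator) or `"arm"` (treatment as a multi-level factor, F-test).
#' @return p-value of the treatment effect.
#' @export
ancova_cross_sectional <- function(dataset, landmark = 3,
                                   factor = c("pooled", "arm")) {
  factor <- match.arg(factor)
  base <- dataset[dataset$time_months == 0,
                  c("patient_id", "arm", "dose_mg", "total")]
  lm_ <- dataset[dataset$time_months == landmark, c("patient_id", "total")]
  m <- match(base$patient_id, lm_$patient_id)
  if (all(is.na(m))) stop("no observations at the landmark time",
                          call. = FALSE)
  df <- data.frame(change = lm_$total[m] - base$total,
                   base = base$total,
                   treat = base$dose_mg > 0,
                   arm = factor(base$arm))
  df <- df[stats::complete.cases(df), ]
  ancova_p(df, factor)
}

#' While-on-treatment ANCOVA
#'
#' As [ancova_cross_sectional()], but the dependent variable is each
#' patient's average change from baseline over all post-baseline visits.
#'
#' @inheritParams ancova_cross_sectional
#' @return p-value of the treatment effect.
#' @export
ancova_wot <- function(dataset, factor = c("pooled", "arm")) {
  factor <- match.arg(factor)
  base <- dataset[dataset$time_months == 0,
                  c("patient_id", "arm", "dose_mg", "total")]
  post <- dataset[dataset$time_months > 0, c("patient_id", "total")]
  if (!nrow(post)) stop("no post-baseline observations", call. = FALSE)
  chg <- post$total - base$total[match(post$patient_id, base$patient_id)]
  avg <- tapply(chg, post$patient_id, mean, na.rm = TRUE)
  m <- match(base$patient_id, as.numeric(names(avg)))
  df <- data.frame(change = as.numeric(avg)[m], base = base$total,
                   treat = base$dose_mg > 0, arm = factor(base$arm))
  df <- df[stats::complete.cases(df), ]
  ancova_p(df, factor)
}

ancova_p <- function(df, factor) {
  if (factor == "pooled") {
    fit <- stats::lm(change ~ treat + base, data = df)
    stats::coef(summary(fit))["treatTRUE", "Pr(>|t|)"]
  } else {
    full <- stats::lm(change ~ arm + base, data = df)
    red <- stats::lm(change ~ base, data = df)
    stats::anova(red, full)[2L, "Pr(>F)"]
  }
}

#' Empirical OFV-difference threshold at a given type-I-error level
#'
#' The calibrated likelihood-ratio cutoff is the upper `alpha` quantile of
#' the OFV differences observed when refitting full and reduced models to
#' trials simulated without a drug effect; applying it back to the null
#' replicates gives a rejection rate of `alpha` by construction.
#'
#' @param null_dofv numeric vector of full-vs-reduced OFV differences from
#'   null (no drug effect) replicates.
#' @param alpha type-I-error level (default 0.05).
#' @return The calibrated threshold.
#' @export
calibrate_dofv <- function(null_dofv, alpha = 0.05) {
  null_dofv <- null_dofv[is.finite(null_dofv)]
  if (length(null_dofv) < 100L)
    warning("fewer than 100 null replicates: the calibrated threshold is ",
            "an unstable percentile estimate", call. = FALSE)
  unname(stats::quantile(null_dofv, 1 - alpha, type = 7))
}

# Set the drug effect(s) of a simulation truth to zero.
null_truth <- function(truth) {
  th <- truth$longitudinal$theta
  th[grep("^drug", names(th))] <- 0
  truth$longitudinal$theta <- th
  truth
}

# One simulated trial under `truth` at sample size n (balanced arms, no
# dropout or item missingness, screening off: the simulation model's
# baseline distribution already describes the trial population).
sse_simulate <- function(truth, n, seed) {
  des <- trial_design(n_patients = n, screening_threshold = -Inf,
                      seed = seed)
  simulate_trial(des, truth)
}

# Fit full and reduced versions of one analysis model; returns dOFV and
# convergence of the pair.
sse_fit_pair <- function(dat, method, banks, control) {
  if (method == "total") {
    red <- fit_total_score(dat, drug_effect = FALSE, control = control)
    full <- fit_total_score(dat, drug_effect = TRUE, start = red,
                            control = control)
  } else {
    bank <- if (method == "uni") banks$uni else banks$bi
    wei <- method == "bi"
    red <- fit_joint(dat, bank, drug_effect = FALSE, estimate_wei = wei,
                     control = control)
    sv <- red$params
    full <- fit_joint(dat, bank, drug_effect = TRUE, estimate_wei = wei,
                      start = c(sv[!vapply(sv, is.null, TRUE)],
                                as.list(stats::setNames(red$iiv_sd,
                                  paste0("om_", names(red$iiv_sd))))),
                      control = control)
  }
  list(dofv = red$ofv - full$ofv,
       converged = full$converged && red$converged)
}

#' Stochastic simulation and estimation power analysis
#'
#' For each sample size and replicate, a trial is simulated from the
#' (item-level) simulation model and analyzed with the requested methods:
#' likelihood-ratio tests of the offset drug effect in the bidimensional
#' IRT (`"bi"`, df = 2), unidimensional IRT (`"uni"`) and total-score
#' (`"total"`) longitudinal models, and the two ANCOVA estimands
#' (`"ancova3m"`, `"ancovawot"`, p < 0.05). Model-based methods use
#' empirically calibrated OFV thresholds from null replicates simulated
#' with the drug effect set to zero; only replicate pairs in which both
#' the full and the reduced model converged enter the power estimate.
#'
#' @param truth item-level [simulation_truth()]; default the reference
#'   bidimensional longitudinal IRT model (lowest AIC).
#' @param n_grid sample sizes (default 33, 66, 99, 137).
#' @param n_reps replicates per sample size (1000 for production use;
#'   smaller values give proportionally wider binomial CIs).
#' @param n_null_reps null replicates for threshold calibration (default
#'   `n_reps`).
#' @param methods subset of `c("bi", "uni", "total", "ancova3m",
#'   "ancovawot")`.
#' @param seed integer seed; replicate seeds are derived from it, so
#'   results do not depend on evaluation order.
#' @param alpha significance level (default 0.05).
#' @param control fit control for the model-based methods.
#' @return Object of class `power_curve`: data.frame `method, n, power,
#'   lo, hi, n_reps, n_converged, threshold`, with 80%-power sample sizes
#'   (isotonic + linear interpolation) as attribute `"n80"`.
#' @export
sse_power <- function(truth = simulation_truth(
                        bank = reference_item_bank("bidimensional"),
                        longitudinal = reference_longitudinal("bidimensional")),
                      n_grid = c(33L, 66L, 99L, 137L), n_reps = 1000L,
                      n_null_reps = n_reps,
                      methods = c("bi", "uni", "total", "ancova3m",
                                  "ancovawot"),
                      seed = 7L, alpha = 0.05, control = list()) {
  methods <- match.arg(methods, several.ok = TRUE)
  model_methods <- intersect(methods, c("bi", "uni", "total"))
  banks <- list(uni = reference_item_bank("unidimensional"),
                bi = reference_item_bank("bidimensional"))
  ctl <- utils::modifyList(list(outer_iter = 100L, outer_rel_tol = 1e-6),
                           control)
  truth0 <- null_truth(truth)
  rows <- list()
  for (n in n_grid) {
    thresholds <- stats::setNames(rep(NA_real_, length(model_methods)),
                                  model_methods)
    if (length(model_methods)) {
      null_dofv <- matrix(NA_real_, n_null_reps, length(model_methods),
                          dimnames = list(NULL, model_methods))
      for (r in seq_len(n_null_reps)) {
        dat <- sse_simulate(truth0, n, seed = seed + 7919L * r + 31L * n)
        for (mth in model_methods) {
          pr <- try(sse_fit_pair(dat, mth, banks, ctl), silent = TRUE)
          if (!inherits(pr, "try-error") && pr$converged)
            null_dofv[r, mth] <- pr$dofv
        }
      }
      for (mth in model_methods)
        thresholds[mth] <- suppressWarnings(
          calibrate_dofv(null_dofv[, mth], alpha))
    }
    hits <- conv <- stats::setNames(rep(0L, length(methods)), methods)
    for (r in seq_len(n_reps)) {
      dat <- sse_simulate(truth, n, seed = seed + 104729L * r + 31L * n)
      for (mth in methods) {
        if (mth %in% model_methods) {
          pr <- try(sse_fit_pair(dat, mth, banks, ctl), silent = TRUE)
          if (inherits(pr, "try-error") || !pr$converged) next
          conv[mth] <- conv[mth] + 1L
          if (is.finite(thresholds[mth]) && pr$dofv > thresholds[mth])
            hits[mth] <- hits[mth] + 1L
        } else {
          p <- if (mth == "ancova3m") ancova_cross_sectional(dat)
               else ancova_wot(dat)
          conv[mth] <- conv[mth] + 1L
          if (p < alpha) hits[mth] <- hits[mth] + 1L
        }
      }
    }
    for (mth in methods) {
      ci <- wilson_ci(hits[mth], conv[mth])
      rows[[length(rows) + 1L]] <- data.frame(
        method = mth, n = n,
        power = if (conv[mth]) hits[mth] / conv[mth] else NA_real_,
        lo = ci[1L], hi = ci[2L], n_reps = n_reps,
        n_converged = conv[mth],
        threshold = if (mth %in% model_methods) thresholds[mth]
                    else stats::qchisq(1 - alpha, 1L))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n80") <- vapply(split(out, out$method), function(s)
    interpolate_n80(s$n, s$power), numeric(1L))
  class(out) <- c("power_curve", "data.frame")
  out
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, level = 0.95) {
  if (!n) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

# Sample size reaching 80% power: pool-adjacent-violators to enforce
# monotone power in n, then linear interpolation.
interpolate_n80 <- function(n, power, target = 0.8) {
  ok <- is.finite(power)
  n <- n[ok]; power <- power[ok]
  if (length(n) < 2L) return(NA_real_)
  o <- order(n); n <- n[o]; power <- power[o]
  # PAVA
  repeat {
    viol <- which(diff(power) < 0)
    if (!length(viol)) break
    i <- viol[1L]
    m <- mean(power[i:(i + 1L)])
    power[i:(i + 1L)] <- m
  }
  if (all(power < target) || all(power > target)) return(NA_real_)
  i <- max(which(power <= target))
  if (power[i] == target) return(n[i])
  if (i == length(n)) return(NA_real_)
  n[i] + (target - power[i]) / (power[i + 1L] - power[i]) *
    (n[i + 1L] - n[i])
}

#' @export
print.power_curve <- function(x, ...) {
  cat("SSE power curves (calibrated thresholds for model-based methods)\n")
  df <- as.data.frame(x)
  df$power <- round(df$power, 3); df$lo <- round(df$lo, 3)
  df$hi <- round(df$hi, 3); df$threshold <- round(df$threshold, 2)
  print(df, row.names = FALSE)
  n80 <- attr(x, "n80")
  ok <- is.finite(n80)
  if (any(ok))
    cat("80%-power sample sizes:",
        paste(names(n80)[ok], round(n80[ok]), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}
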