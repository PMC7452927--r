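# Synthetic trial generator emulating a four-arm, 403-patient, 6-month
# dose-finding design: screening inclusion on total IPSS >= 13 two weeks
# before dosing, visits at 0, 0.5, 1, 2, 3, 4, 5 and 6 months, latent
# disability following baseline + placebo + offset drug, and item scores
# drawn from a graded-response item bank.

.DEFAULT_VISITS <- c(0, 0.5, 1, 2, 3, 4, 5, 6)

#' Trial design
#'
#' @param n_patients number of randomized patients (default 403).
#' @param arms data.frame with columns `label`, `dose_mg`, `allocation`
#'   (fractions summing to 1). Default four arms placebo/10/20/30 mg at
#'   equal allocation; `arms = "reference"` gives the observed arm sizes
#'   98/101/99/105 as allocation fractions.
#' @param visit_times strictly increasing visit times in months, first 0
#'   (baseline).
#' @param screening_threshold minimum total IPSS at screening (default 13);
#'   `-Inf` disables screening.
#' @param item_missingness_rate per-item probability of a missing score.
#' @param dropout_rate per-visit probability of dropping out after baseline.
#' @param seed integer seed; every patient gets an own derived random
#'   stream, so increasing `n_patients` leaves earlier patients unchanged.
#' @return Object of class `trial_design`.
#' @export
trial_design <- function(n_patients = 403L, arms = NULL,
                         visit_times = .DEFAULT_VISITS,
                         screening_threshold = 13,
                         item_missingness_rate = 0, dropout_rate = 0,
                         seed = 1L) {
  if (is.null(arms))
    arms <- data.frame(label = c("placebo", "10mg", "20mg", "30mg"),
                       dose_mg = c(0, 10, 20, 30), allocation = rep(0.25, 4))
  else if (identical(arms, "reference"))
    arms <- data.frame(label = c("placebo", "10mg", "20mg", "30mg"),
                       dose_mg = c(0, 10, 20, 30),
                       allocation = c(98, 101, 99, 105) / 403)
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) stop("need at least one patient", call. = FALSE)
  if (abs(sum(arms$allocation) - 1) > 1e-8)
    stop("allocation fractions must sum to 1", call. = FALSE)
  if (any(arms$allocation < 0))
    stop("allocation fractions must be nonnegative", call. = FALSE)
  if (visit_times[1L] != 0 || is.unsorted(visit_times, strictly = TRUE))
    stop("`visit_times` must be strictly increasing and start at 0 (baseline)",
         call. = FALSE)
  for (r in c(item_missingness_rate, dropout_rate))
    if (r < 0 || r > 1) stop("rates must be in [0, 1]", call. = FALSE)
  structure(list(n_patients = n_patients, arms = arms,
                 visit_times = as.numeric(visit_times),
                 screening_threshold = screening_threshold,
                 item_missingness_rate = item_missingness_rate,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "trial_design")
}

#' Simulation truth
#'
#' Couples an item bank with a longitudinal latent-disability parameter set
#' and covariate distributions into a complete generative model for
#' item-level trial data.
#'
#' @param bank a `grm_item_bank`; its dimensionality must match the
#'   longitudinal parameter set.
#' @param longitudinal list as returned by [reference_longitudinal()]
#'   (components `theta`, `iiv`, `correlations`, `residual`, `covariates`).
#' @param covariate_distributions named list of sampling specs
#'   `list(values, probs)` for each baseline covariate; defaults emulate the
#'   observed quality-of-life score, BPH Impact Index and region mix.
#' @param covariate_centers named centering values (defaults: the medians of
#'   the default distributions).
#' @return Object of class `simulation_truth`.
#' @export
simulation_truth <- function(bank = reference_item_bank("unidimensional"),
                             longitudinal =
                               reference_longitudinal("unidimensional"),
                             covariate_distributions =
                               default_covariate_distributions(),
                             covariate_centers = NULL) {
  stopifnot(inherits(bank, "grm_item_bank"))
  latent_dims <- if ("baseline_v" %in% names(longitudinal$theta)) 2L else 1L
  if (latent_dims != bank$n_dimensions)
    stop("item bank dimensionality does not match longitudinal parameters",
         call. = FALSE)
  cvs <- longitudinal$covariates
  if (!is.null(cvs) && nrow(cvs) &&
      !all(cvs$covariate %in% names(covariate_distributions)))
    stop("every covariate with an effect needs a sampling distribution",
         call. = FALSE)
  if (is.null(covariate_centers))
    covariate_centers <- lapply(covariate_distributions, function(d) {
      cdf <- cumsum(d$probs)
      d$values[which(cdf >= 0.5)[1L]]
    })
  structure(list(bank = bank, longitudinal = longitudinal,
                 covariate_distributions = covariate_distributions,
                 covariate_centers = covariate_centers),
            class = "simulation_truth")
}

#' Default baseline covariate distributions
#'
#' Discrete sampling specs for the quality-of-life score (1-6, median 4),
#' the BPH Impact Index (0-13, median 7) and region (1 = North America,
#' about 60%).
#'
#' @return Named list of `list(values, probs)` specs.
#' @export
default_covariate_distributions <- function() {
  list(qol_base = list(values = 1:6,
                       probs = c(0.02, 0.08, 0.25, 0.35, 0.20, 0.10)),
       bii_base = list(values = 0:13, probs = stats::dbinom(0:13, 13, 0.53)),
       region = list(values = c(0, 1), probs = c(0.4, 0.6)))
}

# Deterministic per-patient stream seeds: stable in patient index so that
# growing the trial does not reshuffle earlier patients.
patient_seed <- function(seed, id) {
  m <- 2147483629
  v <- ((abs(seed) %% m) * 48271) %% m
  as.integer((v + id * 69621) %% m) + 1L
}

# Two sub-seeds per patient: one for population draws (covariates, etas,
# screening), one for post-randomization item responses.
patient_subseeds <- function(seed, id) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(patient_seed(seed, id))
  sample.int(2147483646L, 2L)
}

# Names of the eta dimensions of a longitudinal parameter set.
iiv_names <- function(longitudinal) names(longitudinal$iiv)

# Map theta/iiv to per-dimension structural parameter sets. Returns a list
# of lists with elements baseline, pmax, tprog, wei, drift, drug giving the
# theta names / eta names used on each latent dimension.
dimension_map <- function(longitudinal) {
  th <- names(longitudinal$theta)
  if ("baseline_v" %in% th)
    list(list(baseline = "baseline_v", pmax = "pmax_v", tprog = "tprog_v",
              wei = "wei", drift = "drift", drug = "drug_v",
              eta = c(baseline = "baseline_v", pmax = "pmax",
                      tprog = "tprog", drift = "drift")),
         list(baseline = "baseline_s", pmax = "pmax_s", tprog = "tprog_s",
              wei = "wei", drift = "drift", drug = "drug_s",
              eta = c(baseline = "baseline_s", pmax = "pmax",
                      tprog = "tprog", drift = "drift")))
  else
    list(list(baseline = "baseline", pmax = "pmax", tprog = "tprog",
              wei = "wei", drift = "drift", drug = "drug",
              eta = c(baseline = "baseline", pmax = "pmax",
                      tprog = "tprog", drift = "drift")))
}

# Individual structural parameters on one latent dimension.
# patients: data.frame with covariates and eta_<name> columns.
individual_dim_params <- function(truth, patients, dmap) {
  lg <- truth$longitudinal
  n <- nrow(patients)
  get_theta <- function(nm) unname(lg$theta[[nm]])
  out <- list()
  for (p in c("baseline", "pmax", "tprog", "drift")) {
    th <- get_theta(dmap[[p]])
    val <- rep(th, n)
    cvs <- lg$covariates
    if (!is.null(cvs) && nrow(cvs)) {
      for (r in which(cvs$parameter == dmap[[p]])) {
        dev <- patients[[cvs$covariate[r]]] -
          truth$covariate_centers[[cvs$covariate[r]]]
        if (cvs$form[r] == "multiplicative")
          val <- val * (1 + cvs$coef[r] * dev)
        else val <- val + cvs$coef[r] * dev
      }
    }
    enm <- dmap$eta[[p]]
    sp <- lg$iiv[[enm]]
    if (!is.null(sp)) {
      e <- patients[[paste0("eta_", enm)]]
      if (!is.null(sp$boxcox)) e <- boxcox_eta(e, sp$boxcox)
      if (sp$dist == "lognormal") val <- val * exp(e) else val <- val + e
    }
    out[[p]] <- val
  }
  out$wei <- rep(get_theta(dmap$wei), n)
  out$drug <- rep(get_theta(dmap$drug), n)
  out
}

# Latent disability of given patients at given times on every dimension.
# Returns an n_patients x n_times x n_dims array.
latent_matrix <- function(truth, patients, t) {
  dmaps <- dimension_map(truth$longitudinal)
  active <- patients$dose_mg > 0
  n <- nrow(patients)
  out <- array(0, c(n, length(t), length(dmaps)))
  for (d in seq_along(dmaps)) {
    ip <- individual_dim_params(truth, patients, dmaps[[d]])
    for (v in seq_along(t))
      out[, v, d] <- ip$baseline +
        ip$pmax * (1 - exp(-((log(2) / ip$tprog) * t[v])^ip$wei)) +
        ip$drift * t[v] + ifelse(active & t[v] > 0, ip$drug, 0)
  }
  out
}

#' Generate a trial population
#'
#' Draws arm assignment, baseline covariates and individual random effects
#' for every patient, applying the screening rule by rejection sampling:
#' a screening visit is simulated at the patient's baseline latent value
#' plus an independent N(0, 0.3^2) perturbation, items are scored, and the
#' patient is redrawn until the screening total meets the threshold.
#'
#' @param design a [trial_design()].
#' @param truth a [simulation_truth()].
#' @return data.frame with one row per patient: `patient_id`, `arm`,
#'   `dose_mg`, covariates, `ipss_screen` and `eta_*` columns.
#' @export
generate_population <- function(design, truth) {
  stopifnot(inherits(design, "trial_design"),
            inherits(truth, "simulation_truth"))
  lg <- truth$longitudinal
  V <- iiv_covariance(lg$iiv, lg$correlations)
  arms <- design$arms
  ndim <- truth$bank$n_dimensions
  dmaps <- dimension_map(lg)
  rows <- vector("list", design$n_patients)
  for (i in seq_len(design$n_patients)) {
    ss <- patient_subseeds(design$seed, i)
    set.seed(ss[1L])
    arm_i <- sample.int(nrow(arms), 1L, prob = arms$allocation)
    repeat {
      covs <- lapply(truth$covariate_distributions, function(d)
        sample(d$values, 1L, prob = d$probs))
      eta <- draw_etas(1L, V)
      colnames(eta) <- paste0("eta_", colnames(eta))
      pat <- data.frame(patient_id = i, arm = arms$label[arm_i],
                        dose_mg = arms$dose_mg[arm_i], covs, eta)
      psi0 <- latent_matrix(truth, pat, 0)          # 1 x 1 x ndim
      psi_screen <- psi0[1, 1, ] + stats::rnorm(ndim, 0, 0.3)
      total <- sum(vapply(seq_along(truth$bank$items), function(j)
        grm_simulate_item(truth$bank$items[[j]],
                          psi_screen[bank_dim_index(truth$bank)[j]]),
        integer(1L)))
      if (total >= design$screening_threshold) break
    }
    pat$ipss_screen <- total
    rows[[i]] <- pat
  }
  do.call(rbind, rows)
}

#' Latent disability trajectories
#'
#' Evaluates each patient's latent disability at the given visit times:
#' individual baseline plus individual placebo response plus the offset drug
#' effect on active arms at post-dose times.
#'
#' @param patients population table from [generate_population()].
#' @param truth a [simulation_truth()].
#' @param visit_times visit times in months (nonnegative).
#' @return Long data.frame: `patient_id`, `time_months`, `visit_idx`,
#'   `psi1` (and `psi2` for bidimensional truth).
#' @export
generate_trajectories <- function(patients, truth, visit_times) {
  if (any(visit_times < 0)) stop("negative visit times", call. = FALSE)
  psi <- latent_matrix(truth, patients, visit_times)   # n x nt x ndim
  nt <- length(visit_times)
  n <- nrow(patients)
  out <- data.frame(
    patient_id = rep(patients$patient_id, each = nt),
    time_months = rep(visit_times, n),
    visit_idx = rep(seq_len(nt), n))
  for (d in seq_len(dim(psi)[3L]))
    out[[paste0("psi", d)]] <- as.vector(t(psi[, , d]))
  out
}

#' Item responses from latent trajectories
#'
#' Draws graded-response item scores at every patient-visit, then applies
#' item-level missingness and monotone dropout per the design.
#'
#' @param trajectories output of [generate_trajectories()].
#' @param bank a `grm_item_bank` whose dimensionality matches the
#'   trajectories.
#' @param design a [trial_design()].
#' @param patients population table (supplies arm, dose and covariates).
#' @return Long-format `data.frame` (class `trial_dataset`), one row per
#'   patient-visit with columns `patient_id, arm, dose_mg, time_months,
#'   visit_idx, item1..item7, total, qol_base, bii_base, region`.
#' @export
generate_item_responses <- function(trajectories, bank, design, patients) {
  ndim <- bank$n_dimensions
  psi_cols <- paste0("psi", seq_len(ndim))
  if (!all(psi_cols %in% names(trajectories)))
    stop("trajectory dimensions do not match the item bank", call. = FALSE)
  dimof <- bank_dim_index(bank)
  rows <- vector("list", length(unique(trajectories$patient_id)))
  ids <- unique(trajectories$patient_id)
  for (ii in seq_along(ids)) {
    id <- ids[ii]
    tr <- trajectories[trajectories$patient_id == id, , drop = FALSE]
    ss <- patient_subseeds(design$seed, id)
    set.seed(ss[2L])
    scores <- matrix(NA_integer_, nrow(tr), 7L)
    for (j in 1:7)
      scores[, j] <- grm_simulate_item(bank$items[[j]], tr[[psi_cols[dimof[j]]]])
    if (design$item_missingness_rate > 0)
      scores[matrix(stats::runif(length(scores)) <
                      design$item_missingness_rate, nrow(tr))] <- NA_integer_
    keep <- rep(TRUE, nrow(tr))
    if (design$dropout_rate > 0 && nrow(tr) > 1L) {
      drop_at <- which(stats::runif(nrow(tr) - 1L) < design$dropout_rate)
      if (length(drop_at)) keep[(min(drop_at) + 1L):nrow(tr)] <- FALSE
    }
    pat <- patients[patients$patient_id == id, , drop = FALSE]
    df <- data.frame(patient_id = id, arm = pat$arm, dose_mg = pat$dose_mg,
                     time_months = tr$time_months, visit_idx = tr$visit_idx)
    for (j in 1:7) df[[paste0("item", j)]] <- scores[, j]
    df$total <- rowSums(scores)
    df$qol_base <- pat$qol_base
    df$bii_base <- pat$bii_base
    df$region <- pat$region
    rows[[ii]] <- df[keep, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trial_dataset", "data.frame")
  out
}

#' Simulate a complete item-level trial
#'
#' Convenience wrapper: population (with screening), latent trajectories,
#' and item responses.
#'
#' @inheritParams generate_population
#' @return A `trial_dataset` with the population table attached as
#'   attribute `"patients"`.
#' @export
simulate_trial <- function(design = trial_design(),
                           truth = simulation_truth()) {
  pop <- generate_population(design, truth)
  traj <- generate_trajectories(pop, truth, design$visit_times)
  dat <- generate_item_responses(traj, truth$bank, design, pop)
  attr(dat, "patients") <- pop
  attr(dat, "trajectories") <- traj
  dat
}

#' Simulate an independent-visit (IDVIS) dataset
#'
#' Draws item responses under the generative model assumed by the ICC
#' estimation stage itself: every patient-visit is an independent
#' pseudo-individual whose latent disability comes from the standard normal
#' at baseline and from the shifted post-baseline distribution otherwise.
#' Used for ICC parameter-recovery studies.
#'
#' @param bank a `grm_item_bank`.
#' @param shift a [latent_shift()] matching the bank's dimensionality.
#' @param n_patients number of patients.
#' @param visit_times visit times (first is baseline).
#' @param seed integer seed.
#' @return A `trial_dataset` with all patients labelled `placebo`; the true
#'   latent values are attached as attribute `"psi"`.
#' @export
simulate_idvis_dataset <- function(bank, shift, n_patients = 403L,
                                   visit_times = .DEFAULT_VISITS, seed = 1L) {
  stopifnot(inherits(bank, "grm_item_bank"))
  ndim <- bank$n_dimensions
  set.seed(seed)
  nt <- length(visit_times)
  n <- n_patients * nt
  baseline <- rep(visit_times == 0, n_patients)
  rho <- if (ndim == 2L) shift$correlation else NULL
  psi <- matrix(0, n, ndim)
  if (ndim == 1L) {
    psi[baseline, 1L] <- stats::rnorm(sum(baseline))
    psi[!baseline, 1L] <- stats::rnorm(sum(!baseline), shift$post_mean,
                                       sqrt(shift$post_variance))
  } else {
    C <- matrix(c(1, rho, rho, 1), 2L)
    z <- matrix(stats::rnorm(2L * n), n) %*% chol(C)
    for (d in 1:2) {
      psi[baseline, d] <- z[baseline, d]
      psi[!baseline, d] <- shift$post_mean[d] +
        sqrt(shift$post_variance[d]) * z[!baseline, d]
    }
  }
  dimof <- bank_dim_index(bank)
  df <- data.frame(patient_id = rep(seq_len(n_patients), each = nt),
                   arm = "placebo", dose_mg = 0,
                   time_months = rep(visit_times, n_patients),
                   visit_idx = rep(seq_len(nt), n_patients))
  for (j in 1:7)
    df[[paste0("item", j)]] <- grm_simulate_item(bank$items[[j]],
                                                 psi[, dimof[j]])
  df$total <- rowSums(as.matrix(df[paste0("item", 1:7)]))
  df$qol_base <- NA_real_; df$bii_base <- NA_real_; df$region <- NA_real_
  class(df) <- c("trial_dataset", "data.frame")
  attr(df, "psi") <- psi
  df
}

#' Simulate total-score trial data from the Gaussian summary-score model
#'
#' Generates observed total IPSS directly from the longitudinal total-score
#' model (individual baseline + placebo + drug plus combined
#' proportional/additive Gaussian residual), bypassing the item level.
#' Used for recovery studies of the summary-score model.
#'
#' @param design a [trial_design()] (screening applies to the individual
#'   baseline).
#' @param longitudinal parameter set as from `reference_longitudinal("ipss")`.
#' @param covariate_distributions,covariate_centers as in
#'   [simulation_truth()].
#' @return data.frame `patient_id, arm, dose_mg, time_months, visit_idx,
#'   total, qol_base, bii_base, region`.
#' @export
simulate_total_score_trial <- function(design = trial_design(),
                                       longitudinal =
                                         reference_longitudinal("ipss"),
                                       covariate_distributions =
                                         default_covariate_distributions(),
                                       covariate_centers = NULL) {
  truth <- structure(list(bank = NULL, longitudinal = longitudinal,
                          covariate_distributions = covariate_distributions,
                          covariate_centers = covariate_centers),
                     class = "simulation_truth")
  if (is.null(covariate_centers))
    truth$covariate_centers <- lapply(covariate_distributions, function(d)
      d$values[which(cumsum(d$probs) >= 0.5)[1L]])
  V <- iiv_covariance(longitudinal$iiv, longitudinal$correlations)
  arms <- design$arms
  dmap <- dimension_map(longitudinal)[[1L]]
  res <- longitudinal$residual
  rows <- vector("list", design$n_patients)
  for (i in seq_len(design$n_patients)) {
    ss <- patient_subseeds(design$seed, i)
    set.seed(ss[1L])
    arm_i <- sample.int(nrow(arms), 1L, prob = arms$allocation)
    repeat {
      covs <- lapply(truth$covariate_distributions, function(d)
        sample(d$values, 1L, prob = d$probs))
      eta <- draw_etas(1L, V)
      colnames(eta) <- paste0("eta_", colnames(eta))
      pat <- data.frame(patient_id = i, arm = arms$label[arm_i],
                        dose_mg = arms$dose_mg[arm_i], covs, eta)
      ip <- individual_dim_params(truth, pat, dmap)
      screen <- ip$baseline + stats::rnorm(1L, 0,
        sqrt(res$add^2 + (res$prop * ip$baseline)^2))
      if (screen >= design$screening_threshold) break
    }
    set.seed(ss[2L])
    t <- design$visit_times
    pred <- ip$baseline +
      ip$pmax * (1 - exp(-((log(2) / ip$tprog) * t)^ip$wei)) +
      ip$drift * t + ifelse(pat$dose_mg > 0 & t > 0, ip$drug, 0)
    sd_obs <- sqrt(res$add^2 + (res$prop * pred)^2)
    df <- data.frame(patient_id = i, arm = pat$arm, dose_mg = pat$dose_mg,
                     time_months = t, visit_idx = seq_along(t),
                     total = pred + stats::rnorm(length(t), 0, sd_obs),
                     qol_base = pat$qol_base, bii_base = pat$bii_base,
                     region = pat$region)
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
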