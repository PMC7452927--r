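# Reference parameter sets: graded-response item banks and longitudinal
# model parameters estimated from a four-arm, 403-patient, 6-month
# dose-finding trial in moderate-to-severe BPH-LUTS. They serve as the
# default simulation truth throughout the package. Difficulty values are
# stored as reported: first threshold plus positive increments.

.IPSS_ITEM_LABELS <- c("incomplete emptying", "frequency", "intermittency",
                       "urgency", "weak stream", "straining", "nocturia")

.IPSS_DIMENSION <- c("voiding", "storage", "voiding", "storage",
                     "voiding", "voiding", "storage")

.REF_UNI <- list(
  a   = c(1.38, 0.98, 1.29, 0.92, 1.09, 0.95, 0.49),
  raw = list(c(-4.09, 1.82, 1.68, 1.41, 1.27),
             c(-5.39, 2.64, 2.04, 1.49, 1.55),
             c(-3.77, 1.80, 1.60, 1.08, 1.34),
             c(-3.86, 2.09, 1.68, 1.22, 1.42),
             c(-5.11, 2.31, 1.69, 1.32, 1.12),
             c(-3.10, 1.72, 1.68, 1.67, 1.67),
             c(-7.89, 5.19, 3.52, 2.44, 2.10)),
  post_mean = -1.38, post_variance = 2.22)

.REF_BI <- list(
  a   = c(1.60, 1.40, 1.68, 1.16, 1.36, 1.25, 0.60),
  raw = list(c(-3.40, 1.56, 1.44, 1.20, 1.09),
             c(-4.83, 2.24, 1.80, 1.30, 1.30),
             c(-3.03, 1.48, 1.32, 0.88, 1.10),
             c(-3.65, 1.88, 1.55, 1.12, 1.27),
             c(-4.16, 1.90, 1.40, 1.09, 0.93),
             c(-2.46, 1.38, 1.35, 1.34, 1.34),
             c(-6.93, 4.40, 3.04, 2.09, 1.77)),
  post_mean = c(-1.07, -1.40), post_variance = c(1.61, 2.40),
  correlation = 0.691)

#' Reference IPSS item banks
#'
#' Graded-response parameter sets for the seven IPSS items, estimated from a
#' 403-patient dose-finding trial in moderate-to-severe BPH-LUTS under the
#' independent-visit (IDVIS) scheme. The unidimensional bank places all
#' items on a single disability scale; the bidimensional bank separates
#' voiding (items 1, 3, 5, 6) and storage (items 2, 4, 7) symptoms. These
#' are the package's default simulation truth.
#'
#' @param model `"unidimensional"` or `"bidimensional"`.
#' @return A `grm_item_bank`.
#' @export
reference_item_bank <- function(model = c("unidimensional", "bidimensional")) {
  model <- match.arg(model)
  ref <- if (model == "unidimensional") .REF_UNI else .REF_BI
  ndim <- if (model == "unidimensional") 1L else 2L
  items <- lapply(1:7, function(j)
    item_parameters(j, ref$a[j], thresholds_from_increments(ref$raw[[j]]),
                    dimension = if (ndim == 1L) "general"
                                else .IPSS_DIMENSION[j]))
  item_bank(items, n_dimensions = ndim)
}

#' Reference post-baseline latent shift
#'
#' Mean and variance of the post-baseline latent disability distribution
#' (baseline is fixed at standard normal under IDVIS), plus the
#' inter-dimension correlation for the bidimensional model.
#'
#' @inheritParams reference_item_bank
#' @return A [latent_shift()] object.
#' @export
reference_latent_shift <- function(model = c("unidimensional",
                                             "bidimensional")) {
  model <- match.arg(model)
  ref <- if (model == "unidimensional") .REF_UNI else .REF_BI
  latent_shift(post_mean = ref$post_mean, post_variance = ref$post_variance,
               correlation = if (model == "bidimensional") ref$correlation)
}

#' Reference longitudinal model parameter sets
#'
#' Fixed effects, inter-individual variability (IIV) and residual-error
#' parameters of the three final longitudinal models from the same trial:
#' the total-IPSS model, the unidimensional latent-disability model, and the
#' bidimensional latent-disability model (Weibull placebo time-course with
#' a shape parameter shared across dimensions). IIV percentages are stored
#' as standard deviations (100 * sqrt(variance)); the typical drift is zero
#' in all models. Times are in months.
#'
#' @param model `"ipss"` (total score), `"unidimensional"` or
#'   `"bidimensional"` (latent disability).
#' @return A list with components `theta` (named fixed effects), `iiv`
#'   (named list of per-parameter distribution/sd), `correlations` (named
#'   pairwise IIV correlations), `residual`, and `covariates` (data.frame of
#'   reference covariate coefficients).
#' @export
reference_longitudinal <- function(model = c("ipss", "unidimensional",
                                             "bidimensional")) {
  model <- match.arg(model)
  switch(model,
    ipss = list(
      theta = c(baseline = 19.6, pmax = -4.12, tprog = 15.3, wei = 1,
                drift = 0, drug = -1.98),
      iiv = list(
        baseline = list(dist = "lognormal", sd = 0.137, boxcox = 1.87),
        pmax     = list(dist = "normal",    sd = 1.217),
        tprog    = list(dist = "lognormal", sd = 0.906),
        drift    = list(dist = "normal",    sd = 0.018, boxcox = 39.3)),
      correlations = c("pmax:drift" = 0.431),
      residual = list(prop = 0.109, add = 0),
      covariates = data.frame(
        parameter = c("pmax", "baseline", "baseline", "baseline"),
        covariate = c("qol_base", "bii_base", "qol_base", "region"),
        form = "multiplicative",
        coef = c(0.208, 0.0211, 0.0873, -0.0803))),
    unidimensional = list(
      theta = c(baseline = 0.0283, pmax = -1.03, tprog = 12.3, wei = 1,
                drift = 0, drug = -0.542),
      iiv = list(
        baseline = list(dist = "normal",    sd = 0.759),
        pmax     = list(dist = "normal",    sd = 1.285),
        tprog    = list(dist = "lognormal", sd = 0.524),
        drift    = list(dist = "normal",    sd = 0.007)),
      correlations = c("baseline:pmax" = 0.017, "baseline:drift" = 0.092,
                       "pmax:drift" = 0.34),
      residual = list(prop = 0, add = 0),
      covariates = data.frame(
        parameter = "baseline",
        covariate = c("bii_base", "qol_base", "region"),
        form = "additive",
        coef = c(0.121, 0.325, -0.338))),
    bidimensional = list(
      theta = c(baseline_v = -0.0251, baseline_s = -0.0667,
                pmax_v = -0.75, pmax_s = -0.845,
                tprog_v = 12.9, tprog_s = 13.4, wei = 1.53,
                drift = 0, drug_v = -0.488, drug_s = -0.749),
      iiv = list(
        baseline_v = list(dist = "normal", sd = 0.973),
        baseline_s = list(dist = "normal", sd = 1.288),
        pmax       = list(dist = "normal", sd = 1.456),
        tprog      = list(dist = "lognormal", sd = 0.611),
        drift      = list(dist = "normal", sd = 0.006)),
      correlations = c("baseline_v:baseline_s" = 0.26, "pmax:drift" = 0.40),
      residual = list(prop = 0, add = 0),
      covariates = data.frame(parameter = character(), covariate = character(),
                              form = character(), coef = numeric())))
}

#' IPSS item labels
#'
#' @return Character vector of the seven item short labels, in item order.
#' @export
ipss_item_labels <- function() .IPSS_ITEM_LABELS
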