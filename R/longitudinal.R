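# Structural models for the time course of total IPSS and latent disability.

#' Placebo time-course
#'
#' Placebo response `pmax * (1 - exp(-((log(2)/tprog) * t)^wei)) + drift * t`.
#' With `wei = 1` this is the exponential onset model whose half-life is
#' `tprog`; `wei != 1` gives the Weibull variant. A negative `pmax` is an
#' improvement (symptom scores decrease).
#'
#' @param t time in months, nonnegative.
#' @param pmax maximal placebo response (score or latent units).
#' @param tprog placebo half-life in months, positive.
#' @param wei Weibull shape, positive; 1 = exponential.
#' @param drift linear drift per month.
#' @return Numeric vector the length of `t`.
#' @export
placebo_response <- function(t, pmax, tprog, wei = 1, drift = 0) {
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  if (tprog <= 0) stop("`tprog` must be positive", call. = FALSE)
  if (wei <= 0) stop("`wei` must be positive", call. = FALSE)
  pmax * (1 - exp(-((log(2) / tprog) * t)^wei)) + drift * t
}

#' Typical prediction of the structural longitudinal model
#'
#' `IPSS or disability = baseline + placebo(t) + drug` where the offset drug
#' effect applies on active arms at post-dose times only.
#'
#' @param params named vector or list with `baseline`, `pmax`, `tprog`,
#'   `drug` and optionally `wei` (default 1) and `drift` (default 0).
#' @param arm `"placebo"` or an active-arm label.
#' @param t time in months.
#' @return Numeric vector the length of `t`.
#' @export
structural_prediction <- function(params, arm, t) {
  p <- as.list(params)
  wei <- if (is.null(p$wei)) 1 else p$wei
  drift <- if (is.null(p$drift)) 0 else p$drift
  if (length(arm) != 1L || is.na(arm)) stop("unknown arm", call. = FALSE)
  active <- !identical(tolower(as.character(arm)), "placebo")
  p$baseline + placebo_response(t, p$pmax, p$tprog, wei, drift) +
    if (active) p$drug * (t > 0) else 0
}

#' Box-Cox transformed random effect
#'
#' Maps a normal random effect through `((exp(eta))^shape - 1) / shape`,
#' which skews the implied distribution while keeping `eta = 0` at zero. The
#' `shape -> 0` limit is the identity.
#'
#' @param eta numeric random-effect value(s).
#' @param shape Box-Cox shape parameter.
#' @return Transformed value(s), same length as `eta`.
#' @export
boxcox_eta <- function(eta, shape) {
  if (abs(shape) < 1e-8) return(eta)
  (exp(eta * shape) - 1) / shape
}

# Individual structural parameters from typical values, covariates and etas.
# theta: named fixed effects; iiv: named list(dist, sd, boxcox); covs:
# data.frame(parameter, covariate, form, coef) with centering values in
# `centers`; covariate values and eta matrix are per subject.
individual_parameters <- function(theta, iiv, covs, centers, covariate_values,
                                  eta) {
  n <- nrow(eta)
  out <- matrix(rep(unlist(theta), each = n), nrow = n,
                dimnames = list(NULL, names(theta)))
  if (!is.null(covs) && nrow(covs)) {
    for (r in seq_len(nrow(covs))) {
      par <- covs$parameter[r]; cv <- covs$covariate[r]
      dev <- covariate_values[[cv]] - centers[[cv]]
      if (covs$form[r] == "multiplicative")
        out[, par] <- out[, par] * (1 + covs$coef[r] * dev)
      else
        out[, par] <- out[, par] + covs$coef[r] * dev
    }
  }
  for (par in colnames(eta)) {
    sp <- iiv[[par]]
    e <- eta[, par]
    if (!is.null(sp$boxcox)) e <- boxcox_eta(e, sp$boxcox)
    if (sp$dist == "lognormal") out[, par] <- out[, par] * exp(e)
    else out[, par] <- out[, par] + e
  }
  out
}

# Covariance matrix of the etas from an iiv spec plus named correlations
# ("par1:par2" = rho). Parameters with sd 0 are kept (degenerate) so the
# matrix has one row per IIV parameter.
iiv_covariance <- function(iiv, correlations = NULL) {
  nm <- names(iiv)
  sds <- vapply(iiv, function(s) s$sd, numeric(1L))
  V <- diag(sds^2, nrow = length(sds))
  dimnames(V) <- list(nm, nm)
  if (length(correlations)) {
    for (k in seq_along(correlations)) {
      pr <- strsplit(names(correlations)[k], ":", fixed = TRUE)[[1L]]
      if (!all(pr %in% nm)) next
      V[pr[1L], pr[2L]] <- V[pr[2L], pr[1L]] <-
        correlations[[k]] * sds[pr[1L]] * sds[pr[2L]]
    }
  }
  V
}

# Draw n eta vectors from N(0, V) (V possibly semi-definite).
draw_etas <- function(n, V) {
  ev <- eigen(V, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow = nrow(V))
  z <- matrix(stats::rnorm(n * nrow(V)), n)
  out <- z %*% t(L)
  colnames(out) <- rownames(V)
  out
}
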