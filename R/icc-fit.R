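# Marginal maximum-likelihood estimation of graded-response item
# characteristic curves under the IDVIS scheme: every patient-visit is
# treated as an independent pseudo-individual; the latent disability prior
# is fixed standard normal at baseline and carries an estimated mean/
# variance shift (plus inter-dimension correlation when bidimensional)
# post-baseline. Estimation alternates Bock-Aitkin EM steps for the item
# parameters with closed-form/moment updates of the shift parameters on a
# Gauss-Hermite quadrature grid anchored at the current prior.

#' Post-baseline latent shift
#'
#' @param post_mean per-dimension mean of the post-baseline latent
#'   distribution (baseline is fixed at standard normal).
#' @param post_variance per-dimension variance, positive.
#' @param correlation inter-dimension correlation in (-1, 1); bidimensional
#'   models only, shared between baseline and post-baseline.
#' @return Object of class `latent_shift`.
#' @export
latent_shift <- function(post_mean, post_variance, correlation = NULL) {
  if (length(post_mean) != length(post_variance))
    stop("`post_mean` and `post_variance` must have equal length",
         call. = FALSE)
  if (any(post_variance <= 0))
    stop("`post_variance` must be positive", call. = FALSE)
  if (!is.null(correlation) && abs(correlation) >= 1)
    stop("`correlation` must lie in (-1, 1)", call. = FALSE)
  if (length(post_mean) == 2L && is.null(correlation))
    correlation <- 0
  structure(list(post_mean = as.numeric(post_mean),
                 post_variance = as.numeric(post_variance),
                 correlation = correlation),
            class = "latent_shift")
}

#' Reshape a trial dataset to IDVIS pseudo-individuals
#'
#' Treats every (patient, visit) row as an independent pseudo-individual,
#' tagging each with its baseline/post-baseline origin; the original
#' patient and visit identity are retained so the longitudinal assignment
#' can be reconciled afterwards.
#'
#' @param dataset long-format trial dataset with `patient_id`,
#'   `time_months` and `item1..item7` columns.
#' @return data.frame with `pseudo_id`, `patient_id`, `time_months`,
#'   `visit_idx` (if present), `origin` and the item columns.
#' @export
reshape_idvis <- function(dataset) {
  key <- paste(dataset$patient_id, dataset$time_months)
  if (anyDuplicated(key))
    stop("duplicate (patient, visit) rows: ",
         paste(utils::head(key[duplicated(key)], 3L), collapse = ", "),
         call. = FALSE)
  out <- data.frame(pseudo_id = seq_len(nrow(dataset)),
                    patient_id = dataset$patient_id,
                    time_months = dataset$time_months)
  if (!is.null(dataset$visit_idx)) out$visit_idx <- dataset$visit_idx
  out$origin <- ifelse(dataset$time_months == 0, "baseline", "post")
  for (j in 1:7) out[[paste0("item", j)]] <- dataset[[paste0("item", j)]]
  attr(out, "extra") <- dataset[setdiff(names(dataset),
                                        c(names(out), "pseudo_id"))]
  class(out) <- c("idvis_table", "data.frame")
  out
}

#' Reassemble an IDVIS table into the original long dataset
#'
#' @param pseudo an `idvis_table` from [reshape_idvis()].
#' @return The original long-format dataset (row order preserved).
#' @export
reassemble_idvis <- function(pseudo) {
  stopifnot(inherits(pseudo, "idvis_table"))
  out <- cbind(pseudo[c("patient_id", "time_months",
                        intersect("visit_idx", names(pseudo)),
                        paste0("item", 1:7))],
               attr(pseudo, "extra"))
  rownames(out) <- NULL
  out
}

# --- quadrature -------------------------------------------------------------

# Gauss-Hermite rule (weight exp(-x^2)) via the Golub-Welsch tridiagonal
# eigenproblem.
gh_rule <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- J[cbind(i + 1L, i)] <- sqrt(i / 2)
  ev <- eigen(J, symmetric = TRUE)
  idx <- order(ev$values)
  list(x = ev$values[idx], w = sqrt(pi) * ev$vectors[1L, idx]^2)
}

# Scores matrix (n x 7, NA allowed) from an idvis table or trial dataset.
score_matrix <- function(data) {
  as.matrix(data[paste0("item", 1:7)])
}

# Accumulate per-row log-likelihood over quadrature nodes:
# rows x nodes matrix, L[n, q] = sum_j logP_{j, y_nj}(psi_q).
loglik_nodes <- function(bank, Y, nodes_by_dim) {
  logp <- grm_logprob_nodes(bank, nodes_by_dim)
  n <- nrow(Y); Q <- length(nodes_by_dim[[1L]])
  L <- matrix(0, n, Q)
  for (j in 1:7) {
    y <- Y[, j]
    obs <- which(!is.na(y))
    if (!length(obs)) next
    # t(logp) is 6 x Q; pick the row of each observed category
    L[obs, ] <- L[obs, ] + t(logp[[j]])[y[obs] + 1L, , drop = FALSE]
  }
  L
}

logsumexp_rows <- function(L, logw) {
  M <- L[, 1L]
  for (q in seq_len(ncol(L))[-1L]) M <- pmax(M, L[, q])
  M + log(exp(L - M) %*% exp(logw))[, 1L]
}

# Quadrature grids per origin group. Returns list(base=, post=) each with
# nodes_by_dim (list of per-dimension coordinates, one per node) and log
# weights.
idvis_grids <- function(ndim, shift, rule) {
  make1 <- function(mu, sd) list(nodes_by_dim = list(mu + sqrt(2) * sd * rule$x),
                                 logw = log(rule$w / sqrt(pi)))
  if (ndim == 1L)
    return(list(base = make1(0, 1),
                post = make1(shift$post_mean, sqrt(shift$post_variance))))
  # bidimensional: tensor grid pushed through the covariance Cholesky
  z <- as.matrix(expand.grid(z1 = rule$x, z2 = rule$x))
  lw <- log(as.vector(outer(rule$w, rule$w)) / pi)
  make2 <- function(mu, sd, rho) {
    Lc <- chol(matrix(c(1, rho, rho, 1), 2L))  # upper triangular
    zz <- sqrt(2) * z %*% Lc
    list(nodes_by_dim = list(mu[1L] + sd[1L] * zz[, 1L],
                             mu[2L] + sd[2L] * zz[, 2L]),
         logw = lw)
  }
  rho <- if (is.null(shift$correlation)) 0 else shift$correlation
  list(base = make2(c(0, 0), c(1, 1), rho),
       post = make2(shift$post_mean, sqrt(shift$post_variance), rho))
}

#' Marginal objective function value of an ICC model
#'
#' Minus twice the marginal log-likelihood of a dataset under a
#' graded-response bank and latent shift, integrating latent disability by
#' Gauss-Hermite quadrature anchored at the prior (`"ghq"`) or, for
#' unidimensional banks, adaptive Gauss-Hermite centred at each
#' pseudo-individual's posterior mode (`"agh"`).
#'
#' @param bank a `grm_item_bank`.
#' @param shift a [latent_shift()].
#' @param data trial dataset or IDVIS table.
#' @param method `"ghq"` or `"agh"`.
#' @param nodes quadrature nodes per dimension.
#' @return OFV (numeric scalar), with per-row log-likelihoods as attribute
#'   `"loglik"`.
#' @export
icc_ofv <- function(bank, shift, data, method = c("ghq", "agh"), nodes = 21L) {
  method <- match.arg(method)
  pseudo <- if (inherits(data, "idvis_table")) data else reshape_idvis(data)
  Y <- score_matrix(pseudo)
  base <- pseudo$origin == "baseline"
  ll <- numeric(nrow(Y))
  if (method == "ghq") {
    rule <- gh_rule(nodes)
    grids <- idvis_grids(bank$n_dimensions, shift, rule)
    for (g in c("base", "post")) {
      rows <- if (g == "base") which(base) else which(!base)
      if (!length(rows)) next
      L <- loglik_nodes(bank, Y[rows, , drop = FALSE], grids[[g]]$nodes_by_dim)
      ll[rows] <- logsumexp_rows(L, grids[[g]]$logw)
    }
  } else {
    if (bank$n_dimensions != 1L)
      stop("adaptive quadrature is implemented for unidimensional banks",
           call. = FALSE)
    ll <- agh_loglik_uni(bank, shift, Y, base, nodes)
  }
  structure(-2 * sum(ll), loglik = ll)
}

# --- analytic psi-derivatives of the unidimensional response loglik --------

# Gradient and Hessian in psi of sum_j log P_{j,y_j}(psi), vectorized over
# rows; Y is n x 7, psi length n. Missing scores contribute nothing.
uni_psi_derivs <- function(bank, Y, psi) {
  g <- h <- numeric(length(psi))
  for (j in 1:7) {
    it <- bank$items[[j]]
    y <- Y[, j]
    obs <- which(!is.na(y))
    if (!length(obs)) next
    a <- it$a; th <- it$thresholds; nk <- length(th)
    C <- stats::plogis(outer(psi[obs], th, function(p, b) a * (p - b)))
    dC <- a * C * (1 - C)
    d2C <- a * dC * (1 - 2 * C)
    Cl <- cbind(1, C); Cu <- cbind(C, 0)        # C_k and C_{k+1}, k=0..nk
    dCl <- cbind(0, dC); dCu <- cbind(dC, 0)
    d2Cl <- cbind(0, d2C); d2Cu <- cbind(d2C, 0)
    pick <- cbind(seq_along(obs), y[obs] + 1L)
    P <- pmax(Cl[pick] - Cu[pick], .PROB_FLOOR)
    dP <- dCl[pick] - dCu[pick]
    d2P <- d2Cl[pick] - d2Cu[pick]
    g[obs] <- g[obs] + dP / P
    h[obs] <- h[obs] + d2P / P - (dP / P)^2
  }
  list(g = g, h = h)
}

# Posterior mode and curvature for every row (unidimensional): damped
# Newton on loglik + log prior, with prior mean/sd per row.
uni_posterior_mode <- function(bank, Y, prior_mean, prior_sd,
                               max_iter = 50L, tol = 1e-9) {
  psi <- prior_mean
  for (iter in seq_len(max_iter)) {
    d <- uni_psi_derivs(bank, Y, psi)
    g <- d$g - (psi - prior_mean) / prior_sd^2
    h <- d$h - 1 / prior_sd^2
    step <- -g / h
    step <- pmin(pmax(step, -2), 2)             # damp long steps
    psi <- pmin(pmax(psi + step, -12), 12)
    if (max(abs(step)) < tol) break
  }
  d <- uni_psi_derivs(bank, Y, psi)
  h <- d$h - 1 / prior_sd^2
  list(mode = psi, sd = 1 / sqrt(pmax(-h, 1e-12)))
}

# Adaptive Gauss-Hermite marginal loglik per row, unidimensional.
agh_loglik_uni <- function(bank, shift, Y, base, nodes) {
  prior_mean <- ifelse(base, 0, shift$post_mean)
  prior_sd <- ifelse(base, 1, sqrt(shift$post_variance))
  pm <- uni_posterior_mode(bank, Y, prior_mean, prior_sd)
  rule <- gh_rule(nodes)
  n <- nrow(Y)
  A <- matrix(0, n, nodes)
  for (q in seq_len(nodes)) {
    psi_q <- pm$mode + sqrt(2) * pm$sd * rule$x[q]
    lq <- numeric(n)
    for (j in 1:7) {
      y <- Y[, j]
      obs <- which(!is.na(y))
      if (!length(obs)) next
      p <- category_probabilities(bank$items[[j]], psi_q[obs])
      lq[obs] <- lq[obs] + log(pmax(p[cbind(seq_along(obs), y[obs] + 1L)],
                                    .PROB_FLOOR))
    }
    A[, q] <- log(rule$w[q]) + rule$x[q]^2 + lq +
      stats::dnorm(psi_q, prior_mean, prior_sd, log = TRUE)
  }
  M <- A[, 1L]
  for (q in seq_len(nodes)[-1L]) M <- pmax(M, A[, q])
  log(sqrt(2) * pm$sd) + M + log(rowSums(exp(A - M)))
}

# --- EM machinery -----------------------------------------------------------

# Transformed item parameters <-> natural. Natural: (a, tau1, inc2..inc5).
item_to_trans <- function(it) {
  inc <- diff(it$thresholds)
  c(log(it$a), it$thresholds[1L], log(inc))
}
trans_to_item <- function(z, template) {
  nk <- length(template$thresholds)
  th <- cumsum(c(z[2L], exp(z[3:(nk + 1L)])))
  item_parameters(template$item, exp(z[1L]), th, template$dimension)
}

# Weighted item objective and gradient on the transformed scale.
# Nstat: Q x 6 expected counts at node coordinates `psi` (length Q).
item_em_objective <- function(z, psi, Nstat, nk = 5L) {
  a <- exp(z[1L])
  inc <- exp(z[3:(nk + 1L)])
  th <- cumsum(c(z[2L], inc))
  C <- stats::plogis(outer(psi, th, function(p, b) a * (p - b)))  # Q x nk
  Cl <- cbind(1, C); Cu <- cbind(C, 0)
  P <- pmax(Cl - Cu, .PROB_FLOOR)                                 # Q x (nk+1)
  f <- -sum(Nstat * log(P))
  # gradient
  dC_da_a <- C * (1 - C) * outer(psi, th, "-") * a   # dC/d log a
  dC_dth <- -a * C * (1 - C)                         # dC/d tau_k (own)
  W <- Nstat / P                                     # Q x (nk+1)
  # category c (0..nk): P_c = C_c - C_{c+1}
  # d f/d x = -sum_c W_c (dC_c/dx - dC_{c+1}/dx)
  wdiff <- W[, 1:nk, drop = FALSE] - W[, 2:(nk + 1L), drop = FALSE]  # Q x nk
  g_loga <- sum(wdiff * dC_da_a)
  g_tau <- colSums(wdiff * dC_dth)                   # per absolute tau_k
  g_tau1 <- sum(g_tau)
  g_loginc <- vapply(2:nk, function(m) sum(g_tau[m:nk]) * inc[m - 1L],
                     numeric(1L))
  list(value = f, gradient = c(g_loga, g_tau1, g_loginc))
}

# Starting values from pooled observed cumulative frequencies.
start_bank <- function(Y, template_bank) {
  items <- lapply(seq_along(template_bank$items), function(j) {
    it <- template_bank$items[[j]]
    nk <- length(it$thresholds)
    y <- Y[, j]; y <- y[!is.na(y)]
    tau <- vapply(seq_len(nk), function(k) {
      p <- mean(y >= k)
      -stats::qlogis(min(max(p, 0.005), 0.995))
    }, numeric(1L))
    tau <- cummax(tau + seq_len(nk) * 1e-3)  # enforce strict order
    tau <- tau + seq_len(nk) * 1e-6
    item_parameters(it$item, 1, tau, it$dimension)
  })
  item_bank(items, template_bank$n_dimensions)
}

#' Fit graded-response item characteristic curves by marginal ML (IDVIS)
#'
#' Maximizes the marginal likelihood of item-level responses, integrating
#' latent disability over the fixed standard-normal baseline prior and the
#' estimated post-baseline shifted prior, with every patient-visit treated
#' as an independent pseudo-individual. Estimation uses Bock-Aitkin EM on a
#' Gauss-Hermite grid anchored at the current prior: the M-step updates
#' each item's discrimination and threshold increments (on the log scale)
#' by a quasi-Newton step and the shift parameters from posterior moments.
#'
#' @param data trial dataset or [reshape_idvis()] table; at least two
#'   distinct visits are needed to identify the shift parameters.
#' @param n_dimensions 1 (all items on one disability scale) or 2 (voiding/
#'   storage assignment with an estimated inter-dimension correlation).
#' @param nodes quadrature nodes per dimension (default 41 unidimensional,
#'   13 per dimension bidimensional).
#' @param max_iter,tol EM iteration cap and absolute OFV change tolerance.
#' @param se compute standard errors from the observed information matrix
#'   of the transformed parameters (finite differences, delta method).
#' @param start optional `grm_item_bank` of starting values.
#' @return Object of class `icc_fit`: estimated `bank`, `shift`, `ofv`,
#'   `aic`, `n_params`, `se_table`, `converged`, `shift_identified`,
#'   `n_pseudo` and the EM `trace`.
#' @export
fit_icc <- function(data, n_dimensions = 1L,
                    nodes = if (n_dimensions == 1L) 41L else 13L,
                    max_iter = 500L, tol = 0.01, se = TRUE, start = NULL) {
  pseudo <- if (inherits(data, "idvis_table")) data else reshape_idvis(data)
  Y <- score_matrix(pseudo)
  if (any(Y < 0 | Y > 5, na.rm = TRUE))
    stop("item scores must lie in 0..5", call. = FALSE)
  base <- pseudo$origin == "baseline"
  n <- nrow(Y)
  ndim <- as.integer(n_dimensions)
  shift_identified <- any(!base)

  template <- reference_item_bank(if (ndim == 1L) "unidimensional"
                                  else "bidimensional")
  bank <- if (is.null(start)) start_bank(Y, template) else start
  shift <- if (ndim == 1L) latent_shift(-0.5, 1.5)
           else latent_shift(c(-0.5, -0.5), c(1.5, 1.5), 0.3)
  rule <- gh_rule(nodes)
  dimof <- bank_dim_index(bank)

  ofv_trace <- numeric(0)
  ofv_old <- Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    grids <- idvis_grids(ndim, shift, rule)
    Q <- length(grids$base$nodes_by_dim[[1L]])
    # E-step per origin group
    stats_N <- vector("list", 7L)
    for (j in 1:7) stats_N[[j]] <- matrix(0, 2L * Q, 6L)
    psi_nodes <- lapply(1:7, function(j)
      c(grids$base$nodes_by_dim[[dimof[j]]],
        grids$post$nodes_by_dim[[dimof[j]]]))
    ll_total <- 0
    mom <- list(base = NULL, post = NULL)
    for (g in c("base", "post")) {
      rows <- if (g == "base") which(base) else which(!base)
      if (!length(rows)) next
      grid <- grids[[g]]
      L <- loglik_nodes(bank, Y[rows, , drop = FALSE], grid$nodes_by_dim)
      A <- sweep(L, 2L, grid$logw, "+")
      M <- A[, 1L]
      for (q in seq_len(Q)[-1L]) M <- pmax(M, A[, q])
      lse <- M + log(rowSums(exp(A - M)))
      ll_total <- ll_total + sum(lse)
      post <- exp(A - lse)                       # rows x Q posterior weights
      off <- if (g == "base") 0L else Q
      for (j in 1:7) {
        y <- Y[rows, j]
        for (c in 0:5) {
          sel <- which(y == c)
          if (length(sel))
            stats_N[[j]][off + seq_len(Q), c + 1L] <-
              stats_N[[j]][off + seq_len(Q), c + 1L] +
              colSums(post[sel, , drop = FALSE])
        }
      }
      cs <- colSums(post)
      mom[[g]] <- list(n = length(rows), cs = cs, grid = grid)
    }
    ofv <- -2 * ll_total
    ofv_trace <- c(ofv_trace, ofv)
    if (abs(ofv_old - ofv) < tol) { converged <- TRUE; break }
    ofv_old <- ofv

    # M-step: items
    new_items <- vector("list", 7L)
    for (j in 1:7) {
      z0 <- item_to_trans(bank$items[[j]])
      o <- stats::optim(z0, fn = function(z)
        item_em_objective(z, psi_nodes[[j]], stats_N[[j]])$value,
        gr = function(z)
          item_em_objective(z, psi_nodes[[j]], stats_N[[j]])$gradient,
        method = "BFGS", control = list(maxit = 8L))
      new_items[[j]] <- trans_to_item(o$par, bank$items[[j]])
    }
    bank <- item_bank(new_items, ndim)

    # M-step: shift parameters from posterior moments of the post group
    if (shift_identified) {
      pm <- mom$post
      psi_d <- lapply(seq_len(ndim), function(d) pm$grid$nodes_by_dim[[d]])
      m1 <- vapply(psi_d, function(p) sum(pm$cs * p) / pm$n, numeric(1L))
      m2 <- vapply(seq_len(ndim), function(d)
        sum(pm$cs * psi_d[[d]]^2) / pm$n, numeric(1L))
      v <- pmax(m2 - m1^2, 1e-4)
      if (ndim == 1L) shift <- latent_shift(m1, v)
      else {
        x12_post <- sum(pm$cs * psi_d[[1L]] * psi_d[[2L]]) / pm$n
        r_post <- (x12_post - m1[1L] * m1[2L]) / sqrt(v[1L] * v[2L])
        r <- r_post
        if (!is.null(mom$base)) {
          bm <- mom$base
          b1 <- sum(bm$cs * bm$grid$nodes_by_dim[[1L]]) / bm$n
          b2 <- sum(bm$cs * bm$grid$nodes_by_dim[[2L]]) / bm$n
          b12 <- sum(bm$cs * bm$grid$nodes_by_dim[[1L]] *
                       bm$grid$nodes_by_dim[[2L]]) / bm$n
          bv1 <- max(sum(bm$cs * bm$grid$nodes_by_dim[[1L]]^2) / bm$n - b1^2,
                     1e-4)
          bv2 <- max(sum(bm$cs * bm$grid$nodes_by_dim[[2L]]^2) / bm$n - b2^2,
                     1e-4)
          r_base <- (b12 - b1 * b2) / sqrt(bv1 * bv2)
          r <- (pm$n * r_post + bm$n * r_base) / (pm$n + bm$n)
        }
        shift <- latent_shift(m1, v, min(max(r, -0.98), 0.98))
      }
    }

    # the likelihood is nearly invariant under a joint rescaling of the
    # latent scale (a -> a/c, thresholds and shift moments scaled up by c),
    # with curvature coming from the baseline rows only; EM crawls along
    # this ridge, so the scale is resolved by a direct 1-D search on the
    # quadrature OFV every iteration
    if (shift_identified && ndim == 1L) {
      rescaled <- function(cc)
        list(bank = item_bank(lapply(bank$items, function(it)
               item_parameters(it$item, it$a / cc, it$thresholds * cc,
                               it$dimension)), 1L),
             shift = latent_shift(shift$post_mean * cc,
                                  shift$post_variance * cc^2))
      sc <- stats::optimize(function(logc) {
        p <- rescaled(exp(logc))
        icc_ofv(p$bank, p$shift, pseudo, method = "ghq", nodes = nodes)[1L]
      }, c(-0.2, 0.2), tol = 1e-4)
      if (sc$objective < ofv) {
        p <- rescaled(exp(sc$minimum))
        bank <- p$bank
        shift <- p$shift
      }
    }
  }

  n_params <- 7L + 35L +
    if (shift_identified) (if (ndim == 1L) 2L else 5L) else 0L
  fit <- structure(list(
    bank = bank,
    shift = if (shift_identified) shift else
      latent_shift(rep(NA_real_, ndim), rep(1, ndim),
                   if (ndim == 2L) NA_real_ else NULL),
    ofv = ofv, aic = ofv + 2 * n_params, n_params = n_params,
    converged = converged, shift_identified = shift_identified,
    n_pseudo = n, n_dimensions = ndim, nodes = nodes,
    trace = ofv_trace, se_table = NULL), class = "icc_fit")
  if (!shift_identified)
    warning("no post-baseline rows: shift parameters are not identified",
            call. = FALSE)
  if (se && shift_identified) fit$se_table <- icc_se_table(fit, pseudo)
  fit
}

# Pack/unpack the full transformed parameter vector of an icc_fit.
icc_pack <- function(bank, shift, ndim) {
  z <- unlist(lapply(bank$items, item_to_trans))
  if (ndim == 1L) c(z, shift$post_mean, log(shift$post_variance))
  else c(z, shift$post_mean, log(shift$post_variance), atanh(shift$correlation))
}
icc_unpack <- function(z, template_bank, ndim) {
  items <- vector("list", 7L)
  for (j in 1:7)
    items[[j]] <- trans_to_item(z[(j - 1L) * 6L + 1:6],
                                template_bank$items[[j]])
  bank <- item_bank(items, ndim)
  if (ndim == 1L)
    list(bank = bank, shift = latent_shift(z[43L], exp(z[44L])))
  else
    list(bank = bank,
         shift = latent_shift(z[43:44], exp(z[45:46]), tanh(z[47L])))
}

# Standard errors from a finite-difference Hessian of the quadrature OFV on
# the transformed scale, mapped back by the delta method.
icc_se_table <- function(fit, pseudo, h = 1e-3) {
  ndim <- fit$n_dimensions
  z0 <- icc_pack(fit$bank, fit$shift, ndim)
  f <- function(z) {
    p <- icc_unpack(z, fit$bank, ndim)
    0.5 * icc_ofv(p$bank, p$shift, pseudo, method = "ghq",
                  nodes = fit$nodes)[1L]          # negative loglik
  }
  np <- length(z0)
  H <- matrix(0, np, np)
  f0 <- f(z0)
  fp <- fm <- numeric(np)
  for (i in seq_len(np)) {
    zp <- z0; zp[i] <- zp[i] + h
    zm <- z0; zm[i] <- zm[i] - h
    fp[i] <- f(zp); fm[i] <- f(zm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  for (i in seq_len(np - 1L)) for (k in (i + 1L):np) {
    zpp <- z0; zpp[c(i, k)] <- zpp[c(i, k)] + h
    H[i, k] <- H[k, i] <- (f(zpp) - fp[i] - fp[k] + f0) / h^2
  }
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, np, np))
  se_z <- sqrt(pmax(diag(V), 0))
  # delta-method back-transform and natural-parameter names
  nat <- icc_param_table(fit$bank, fit$shift, ndim)
  deriv <- icc_trans_jacobian(z0, ndim)
  nat$se <- se_z * deriv
  nat
}

# natural parameter table (reported scale: a, raw difficulty values, shift)
icc_param_table <- function(bank, shift, ndim) {
  rows <- list()
  for (j in 1:7) {
    it <- bank$items[[j]]
    raw <- c(it$thresholds[1L], diff(it$thresholds))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = c(sprintf("a%d", j), sprintf("b%d_%d", j, 1:5)),
      estimate = c(it$a, raw))
  }
  sh <- if (ndim == 1L)
    data.frame(parameter = c("post_mean", "post_variance"),
               estimate = c(shift$post_mean, shift$post_variance))
  else
    data.frame(parameter = c("post_mean1", "post_mean2", "post_variance1",
                             "post_variance2", "correlation"),
               estimate = c(shift$post_mean, shift$post_variance,
                            shift$correlation))
  out <- rbind(do.call(rbind, rows), sh)
  rownames(out) <- NULL
  out
}

# |d natural / d transformed| for the diagonal delta method.
icc_trans_jacobian <- function(z, ndim) {
  d <- numeric(length(z))
  for (j in 1:7) {
    i0 <- (j - 1L) * 6L
    d[i0 + 1L] <- exp(z[i0 + 1L])          # a = exp(log a)
    d[i0 + 2L] <- 1                        # first threshold
    d[i0 + 3:6] <- exp(z[i0 + 3:6])        # increments
  }
  if (ndim == 1L) d[43:44] <- c(1, exp(z[44L]))
  else d[43:47] <- c(1, 1, exp(z[45:46]), 1 / cosh(z[47L])^2)
  d
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf(paste0("IDVIS graded-response ICC fit (%d-dimensional): ",
                     "%d pseudo-individuals\n"),
              x$n_dimensions, x$n_pseudo))
  cat(sprintf("  %d fixed effects, OFV = %.2f, AIC = %.2f, converged: %s\n",
              x$n_params, x$ofv, x$aic, x$converged))
  print(x$bank)
  if (x$shift_identified) {
    cat("Post-baseline shift: mean",
        paste(signif(x$shift$post_mean, 4), collapse = ", "),
        "; variance", paste(signif(x$shift$post_variance, 4), collapse = ", "))
    if (!is.null(x$shift$correlation))
      cat(" ; correlation", signif(x$shift$correlation, 4))
    cat("\n")
  }
  invisible(x)
}

# --- empirical Bayes estimates ---------------------------------------------

#' Empirical Bayes (MAP) disability estimate for one response pattern
#'
#' Maximizes the response log-likelihood plus the log prior implied by the
#' IDVIS origin (standard normal at baseline, shifted post-baseline) and
#' reports the curvature-based standard error. Falls back to a grid search
#' over \[-10, 10\] if the Newton iteration fails.
#'
#' @param bank fitted `grm_item_bank`.
#' @param shift fitted [latent_shift()].
#' @param responses integer scores of the 7 items (NA allowed).
#' @param origin `"baseline"` or `"post"`.
#' @return list with `ebe` and `se` (per dimension).
#' @export
estimate_ebe <- function(bank, shift, responses, origin = "post") {
  Y <- matrix(as.integer(responses), 1L)
  res <- ebe_table_internal(bank, shift, Y, origin == "baseline")
  list(ebe = drop(res$ebe), se = drop(res$se))
}

# Vectorized MAP + SE for all rows. Returns list(ebe = n x ndim, se = ...).
ebe_table_internal <- function(bank, shift, Y, base) {
  ndim <- bank$n_dimensions
  n <- nrow(Y)
  if (ndim == 1L) {
    prior_mean <- ifelse(base, 0, shift$post_mean)
    prior_sd <- ifelse(base, 1, sqrt(shift$post_variance))
    pm <- uni_posterior_mode(bank, Y, prior_mean, prior_sd)
    bad <- !is.finite(pm$mode) | !is.finite(pm$sd)
    if (any(bad)) {                        # brute-force grid fallback
      grid <- seq(-10, 10, by = 0.001)
      for (i in which(bad)) {
        lp <- vapply(grid, function(p)
          response_loglik(bank, p, Y[i, ]), numeric(1L)) +
          stats::dnorm(grid, prior_mean[i], prior_sd[i], log = TRUE)
        pm$mode[i] <- grid[which.max(lp)]
        pm$sd[i] <- prior_sd[i]
      }
    }
    return(list(ebe = matrix(pm$mode), se = matrix(pm$sd)))
  }
  # bidimensional: damped Newton on both coordinates; the likelihood is
  # separable across dimensions, the prior precision couples them.
  rho <- if (is.null(shift$correlation)) 0 else shift$correlation
  prior_mean <- cbind(ifelse(base, 0, shift$post_mean[1L]),
                      ifelse(base, 0, shift$post_mean[2L]))
  prior_sd <- cbind(ifelse(base, 1, sqrt(shift$post_variance[1L])),
                    ifelse(base, 1, sqrt(shift$post_variance[2L])))
  dimof <- bank_dim_index(bank)
  sub_bank <- function(d) {
    items <- bank$items[dimof == d]
    structure(list(items = items, n_dimensions = 1L),
              class = "grm_item_bank")
  }
  banks <- list(sub_bank(1L), sub_bank(2L))
  Ys <- list(Y[, dimof == 1L, drop = FALSE], Y[, dimof == 2L, drop = FALSE])
  psi <- prior_mean
  detfac <- 1 - rho^2
  for (iter in 1:60) {
    gh <- lapply(1:2, function(d)
      bi_subderivs(banks[[d]], Ys[[d]], psi[, d]))
    # prior gradient: -Sigma^{-1} (psi - mu), Sigma = D R D
    z1 <- (psi[, 1L] - prior_mean[, 1L]) / prior_sd[, 1L]
    z2 <- (psi[, 2L] - prior_mean[, 2L]) / prior_sd[, 2L]
    g1 <- gh[[1L]]$g - (z1 - rho * z2) / (detfac * prior_sd[, 1L])
    g2 <- gh[[2L]]$g - (z2 - rho * z1) / (detfac * prior_sd[, 2L])
    h11 <- gh[[1L]]$h - 1 / (detfac * prior_sd[, 1L]^2)
    h22 <- gh[[2L]]$h - 1 / (detfac * prior_sd[, 2L]^2)
    h12 <- rho / (detfac * prior_sd[, 1L] * prior_sd[, 2L])
    det <- h11 * h22 - h12^2
    s1 <- -(h22 * g1 - h12 * g2) / det
    s2 <- -(h11 * g2 - h12 * g1) / det
    s1 <- pmin(pmax(s1, -2), 2); s2 <- pmin(pmax(s2, -2), 2)
    psi[, 1L] <- pmin(pmax(psi[, 1L] + s1, -12), 12)
    psi[, 2L] <- pmin(pmax(psi[, 2L] + s2, -12), 12)
    if (max(abs(c(s1, s2))) < 1e-9) break
  }
  gh <- lapply(1:2, function(d) bi_subderivs(banks[[d]], Ys[[d]], psi[, d]))
  h11 <- gh[[1L]]$h - 1 / (detfac * prior_sd[, 1L]^2)
  h22 <- gh[[2L]]$h - 1 / (detfac * prior_sd[, 2L]^2)
  h12 <- rho / (detfac * prior_sd[, 1L] * prior_sd[, 2L])
  det <- h11 * h22 - h12^2
  se <- cbind(sqrt(pmax(-h22 / det, 1e-12)), sqrt(pmax(-h11 / det, 1e-12)))
  list(ebe = psi, se = se)
}

bi_subderivs <- function(bank1, Ysub, psi) {
  # reuse the unidimensional derivative kernel on a sub-bank
  g <- h <- numeric(length(psi))
  for (j in seq_along(bank1$items)) {
    it <- bank1$items[[j]]
    y <- Ysub[, j]
    obs <- which(!is.na(y))
    if (!length(obs)) next
    a <- it$a; th <- it$thresholds
    C <- stats::plogis(outer(psi[obs], th, function(p, b) a * (p - b)))
    dC <- a * C * (1 - C); d2C <- a * dC * (1 - 2 * C)
    Cl <- cbind(1, C); Cu <- cbind(C, 0)
    dCl <- cbind(0, dC); dCu <- cbind(dC, 0)
    d2Cl <- cbind(0, d2C); d2Cu <- cbind(d2C, 0)
    pick <- cbind(seq_along(obs), y[obs] + 1L)
    P <- pmax(Cl[pick] - Cu[pick], .PROB_FLOOR)
    dP <- dCl[pick] - dCu[pick]; d2P <- d2Cl[pick] - d2Cu[pick]
    g[obs] <- g[obs] + dP / P
    h[obs] <- h[obs] + d2P / P - (dP / P)^2
  }
  list(g = g, h = h)
}

#' Per patient-visit disability estimates from an ICC fit
#'
#' @param fit an `icc_fit`.
#' @param data the trial dataset or IDVIS table the fit was made on.
#' @return data.frame `patient_id, time_months, origin, dim, ebe, se` with
#'   one row per pseudo-individual and dimension (class `ebe_table`).
#' @export
disability_estimates <- function(fit, data) {
  pseudo <- if (inherits(data, "idvis_table")) data else reshape_idvis(data)
  Y <- score_matrix(pseudo)
  base <- pseudo$origin == "baseline"
  res <- ebe_table_internal(fit$bank, fit$shift, Y, base)
  ndim <- fit$n_dimensions
  out <- do.call(rbind, lapply(seq_len(ndim), function(d)
    data.frame(patient_id = pseudo$patient_id,
               time_months = pseudo$time_months,
               origin = pseudo$origin, dim = d,
               ebe = res$ebe[, d], se = res$se[, d])))
  class(out) <- c("ebe_table", "data.frame")
  out
}

#' Eta-shrinkage of disability estimates
#'
#' SD-based shrinkage: typical shrinkage is `1 - SD(ebe) / SD(prior)` with
#' every estimate standardized by its origin's prior; individual shrinkage
#' is `1 - se_i / SD(prior_i)`, summarized by a normal-approximation 95%
#' confidence interval of its mean and the range.
#'
#' @param fit an `icc_fit`.
#' @param estimates an `ebe_table` from [disability_estimates()].
#' @return list per dimension with `typical`, `individual_mean`,
#'   `individual_ci`, `individual_range`.
#' @export
shrinkage <- function(fit, estimates) {
  if (nrow(estimates) < 2L) stop("need at least two estimates", call. = FALSE)
  lapply(seq_len(fit$n_dimensions), function(d) {
    e <- estimates[estimates$dim == d, ]
    prior_sd <- ifelse(e$origin == "baseline", 1,
                       sqrt(fit$shift$post_variance[d]))
    prior_mean <- ifelse(e$origin == "baseline", 0, fit$shift$post_mean[d])
    z <- (e$ebe - prior_mean) / prior_sd
    ind <- 1 - e$se / prior_sd
    m <- mean(ind); s <- stats::sd(ind) / sqrt(length(ind))
    list(typical = 1 - stats::sd(z),
         individual_mean = m,
         individual_ci = c(m - 1.96 * s, m + 1.96 * s),
         individual_range = range(ind))
  })
}
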