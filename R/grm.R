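# Guard against log(0): category probabilities are floored at this value
# inside logs so extreme latent values never produce -Inf/NaN.
.PROB_FLOOR <- 1e-300

#' Item parameters for one graded-response item
#'
#' Bundles the discrimination (slope) and ordered category thresholds of a
#' single questionnaire item under Samejima's graded response model, together
#' with the latent dimension the item loads on. Higher latent values mean
#' greater disability, so every cumulative score probability increases with
#' the latent variable.
#'
#' @param item integer item index (1-7 for the IPSS).
#' @param a discrimination parameter, strictly positive.
#' @param thresholds strictly increasing numeric vector of category
#'   thresholds on the latent scale (5 for a 0-5 item).
#' @param dimension latent dimension label: `"general"` for unidimensional
#'   banks, `"voiding"` or `"storage"` for bidimensional ones.
#' @return An object of class `grm_item`.
#' @seealso [thresholds_from_increments()], [item_bank()]
#' @export
item_parameters <- function(item, a, thresholds,
                            dimension = c("general", "voiding", "storage")) {
  dimension <- match.arg(dimension)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("discrimination `a` must be a single positive number", call. = FALSE)
  if (!is.numeric(thresholds) || length(thresholds) < 1L ||
      any(!is.finite(thresholds)))
    stop("`thresholds` must be a finite numeric vector", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  structure(
    list(item = as.integer(item), a = as.numeric(a),
         thresholds = as.numeric(thresholds), dimension = dimension),
    class = "grm_item")
}

#' Convert reported difficulty values to ordered thresholds
#'
#' Published difficulty tables for graded items often report the location of
#' the first threshold followed by positive increments between successive
#' thresholds (which keeps the estimated parameters ordered by
#' construction). This helper converts such a vector to absolute threshold
#' locations by cumulative summation.
#'
#' @param raw numeric vector: first element is the first threshold, the
#'   remaining elements are strictly positive increments.
#' @return Strictly increasing numeric vector of thresholds, same length.
#' @examples
#' thresholds_from_increments(c(-4.09, 1.82, 1.68, 1.41, 1.27))
#' @export
thresholds_from_increments <- function(raw) {
  if (!is.numeric(raw) || length(raw) < 1L || any(!is.finite(raw)))
    stop("`raw` must be a finite numeric vector", call. = FALSE)
  if (length(raw) > 1L && any(raw[-1L] <= 0))
    stop("increments (elements 2..n of `raw`) must be strictly positive: ",
         "a non-positive increment would give unordered thresholds and ",
         "negative category probabilities", call. = FALSE)
  cumsum(raw)
}

#' Assemble an item bank
#'
#' @param items list of [item_parameters()] objects with unique item indices.
#' @param n_dimensions 1 or 2. For two dimensions every item must be tagged
#'   `"voiding"` or `"storage"`; the canonical IPSS assignment puts items
#'   1, 3, 5, 6 (emptying, intermittency, weak stream, straining) on the
#'   voiding dimension and items 2, 4, 7 (frequency, urgency, nocturia) on
#'   the storage dimension.
#' @return Object of class `grm_item_bank`.
#' @export
item_bank <- function(items, n_dimensions = 1L) {
  if (!all(vapply(items, inherits, logical(1L), "grm_item")))
    stop("`items` must be a list of grm_item objects", call. = FALSE)
  idx <- vapply(items, `[[`, integer(1L), "item")
  if (anyDuplicated(idx))
    stop("item indices must be unique", call. = FALSE)
  items <- items[order(idx)]
  n_dimensions <- as.integer(n_dimensions)
  if (!n_dimensions %in% c(1L, 2L))
    stop("`n_dimensions` must be 1 or 2", call. = FALSE)
  dims <- vapply(items, `[[`, character(1L), "dimension")
  if (n_dimensions == 2L) {
    if (any(dims == "general"))
      stop("bidimensional banks need every item tagged voiding/storage",
           call. = FALSE)
  }
  structure(list(items = items, n_dimensions = n_dimensions),
            class = "grm_item_bank")
}

#' @export
print.grm_item_bank <- function(x, ...) {
  cat(sprintf("Graded-response item bank: %d items, %d latent dimension%s\n",
              length(x$items), x$n_dimensions,
              if (x$n_dimensions > 1L) "s" else ""))
  df <- bank_to_table(x)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tabulate an item bank
#'
#' @param bank a `grm_item_bank`.
#' @return data.frame with one row per item: index, dimension,
#'   discrimination and absolute thresholds `tau1..tauK`.
#' @export
bank_to_table <- function(bank) {
  stopifnot(inherits(bank, "grm_item_bank"))
  rows <- lapply(bank$items, function(it) {
    th <- it$thresholds
    out <- data.frame(item = it$item, dimension = it$dimension, a = it$a)
    for (k in seq_along(th)) out[[paste0("tau", k)]] <- th[k]
    out
  })
  do.call(rbind, rows)
}

# Column index (1 or 2) of each item's latent coordinate.
bank_dim_index <- function(bank) {
  if (bank$n_dimensions == 1L) rep(1L, length(bank$items))
  else ifelse(vapply(bank$items, `[[`, character(1L), "dimension") ==
                "voiding", 1L, 2L)
}

#' Cumulative probability of scoring at least k
#'
#' Evaluates `P(Y >= k) = plogis(a * (psi - tau_k))`, the graded-response
#' cumulative response curve for one item.
#'
#' @param item a `grm_item`.
#' @param psi latent disability value(s); for bidimensional banks pass the
#'   coordinate of the item's own dimension.
#' @param k category, 1-based (1..5 for the IPSS).
#' @return Probability vector the length of `psi`.
#' @export
cumulative_probability <- function(item, psi, k) {
  stopifnot(inherits(item, "grm_item"))
  if (length(k) != 1L || k < 1L || k > length(item$thresholds))
    stop("`k` must be a single category between 1 and ",
         length(item$thresholds), call. = FALSE)
  stats::plogis(item$a * (psi - item$thresholds[k]))
}

#' Category probabilities of an item at given latent values
#'
#' Differences of adjacent cumulative curves: `P(Y = k) =
#' P(Y >= k) - P(Y >= k + 1)`, with `P(Y = 0) = 1 - P(Y >= 1)` and the top
#' category equal to its cumulative probability.
#'
#' @inheritParams cumulative_probability
#' @return Matrix with `length(psi)` rows and `K + 1` columns for scores
#'   `0..K`; rows sum to one.
#' @export
category_probabilities <- function(item, psi) {
  stopifnot(inherits(item, "grm_item"))
  cum <- stats::plogis(outer(psi, item$thresholds, function(p, b)
    item$a * (p - b)))
  nk <- length(item$thresholds)
  out <- cbind(1 - cum[, 1L, drop = FALSE],
               if (nk > 1L) cum[, -nk, drop = FALSE] - cum[, -1L, drop = FALSE],
               cum[, nk, drop = FALSE])
  colnames(out) <- as.character(0:nk)
  # tiny negatives can arise from floating cancellation at extreme psi
  out[out < 0] <- 0
  out
}

#' Expected item score
#'
#' Mean of the category distribution, `sum_k k P(Y = k)`; strictly increasing
#' in latent disability.
#'
#' @inheritParams cumulative_probability
#' @return Numeric vector the length of `psi`, in `[0, K]`.
#' @export
expected_score <- function(item, psi) {
  p <- category_probabilities(item, psi)
  drop(p %*% (0:(ncol(p) - 1L)))
}

#' Fisher information of an item
#'
#' Fisher information of one graded item about the latent variable,
#' `sum_k (dP_k/dpsi)^2 / P_k` over all categories — the negative expected
#' second derivative of the item log-likelihood.
#'
#' @inheritParams cumulative_probability
#' @return Nonnegative numeric vector the length of `psi`.
#' @export
item_information <- function(item, psi) {
  stopifnot(inherits(item, "grm_item"))
  a <- item$a
  cum <- stats::plogis(outer(psi, item$thresholds, function(p, b) a * (p - b)))
  dcum <- a * cum * (1 - cum)                      # derivative of each curve
  nk <- length(item$thresholds)
  p <- cbind(1 - cum[, 1L, drop = FALSE],
             if (nk > 1L) cum[, -nk, drop = FALSE] - cum[, -1L, drop = FALSE],
             cum[, nk, drop = FALSE])
  dp <- cbind(-dcum[, 1L, drop = FALSE],
              if (nk > 1L) dcum[, -nk, drop = FALSE] - dcum[, -1L, drop = FALSE],
              dcum[, nk, drop = FALSE])
  rowSums(dp^2 / pmax(p, .PROB_FLOOR))
}

#' Response-pattern log-likelihood
#'
#' Log-likelihood of a (possibly incomplete) 7-item response pattern at a
#' given latent position. Missing items contribute zero (missing at random).
#'
#' @param bank a `grm_item_bank`.
#' @param psi numeric latent vector, one value per bank dimension.
#' @param responses integer vector of item scores in `0..5`, `NA` allowed,
#'   ordered by item index.
#' @return Single log-likelihood value.
#' @export
response_loglik <- function(bank, psi, responses) {
  stopifnot(inherits(bank, "grm_item_bank"))
  if (length(psi) != bank$n_dimensions)
    stop("`psi` must have one coordinate per bank dimension", call. = FALSE)
  if (length(responses) != length(bank$items))
    stop("`responses` must have one score per item", call. = FALSE)
  dimof <- bank_dim_index(bank)
  ll <- 0
  for (j in seq_along(bank$items)) {
    y <- responses[j]
    if (is.na(y)) next
    nk <- length(bank$items[[j]]$thresholds)
    if (y < 0 || y > nk || y != round(y))
      stop("score for item ", j, " outside 0..", nk, call. = FALSE)
    p <- category_probabilities(bank$items[[j]], psi[dimof[j]])[1L, y + 1L]
    ll <- ll + log(max(p, .PROB_FLOOR))
  }
  ll
}

# --- fast internal kernels used by estimation ------------------------------

# log category probability table: list over items of (n_nodes x 6) matrices
# evaluated at a vector of latent nodes (per item dimension coordinates).
grm_logprob_nodes <- function(bank, nodes_by_dim) {
  dimof <- bank_dim_index(bank)
  lapply(seq_along(bank$items), function(j) {
    p <- category_probabilities(bank$items[[j]], nodes_by_dim[[dimof[j]]])
    log(pmax(p, .PROB_FLOOR))
  })
}

# Simulate scores for one item at latent values psi.
grm_simulate_item <- function(item, psi) {
  p <- category_probabilities(item, psi)
  cp <- p %*% upper.tri(diag(ncol(p)), diag = TRUE)  # row-wise cumsum
  u <- stats::runif(length(psi))
  as.integer(pmin(rowSums(u > cp), ncol(p) - 1L))
}
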