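#' Latent class model estimation for categorical indicators
#'
#' Weighted maximum-likelihood estimation of the standard latent class
#' model
#' \deqn{P(y_i) = \sum_{k=1}^K \pi_k \prod_{j=1}^J P(y_{ij} \mid X = k),}
#' by EM, maximizing the weighted log-likelihood
#' \eqn{\sum_i w_i \log P(y_i)}. With unit weights this is ordinary ML;
#' with posterior weights it estimates the node-conditional model used at
#' each split of a latent class tree.
#'
#' @param data an [lc_data] object
#' @param K number of classes (>= 1)
#' @param n_starts number of random EM initializations; the best final
#'   log-likelihood is kept
#' @param max_iter maximum EM iterations per start
#' @param tol relative log-likelihood change below which a start is
#'   declared converged
#' @param seed master seed; start-specific seeds are derived from it
#'   deterministically, so results are reproducible
#' @param prob_floor lower floor applied to response probabilities after
#'   each M-step (rows renormalized), preventing log(0) boundary estimates
#' @param ic_n sample size used in the BIC penalty: `"total"` (the number
#'   of rows, i.e. the root sample size — the printed-formula convention)
#'   or `"effective"` (sum of the case weights)
#' @return an object of class `lc_fit` with elements `params` ([lc_params]),
#'   `loglik`, `n_params`, `n_cases_effective`, `n_total`, `bic`, `aic`,
#'   `posteriors` (N x K), `converged`, `n_iterations`, `n_starts_used`,
#'   `seed`
#' @examples
#' d <- simulate_lc(200, c(.5, .5), rbind(rep(.9, 4), rep(.1, 4)), seed = 1)
#' f <- em_fit(d, 2, n_starts = 4, seed = 1)
#' f$params$proportions
#' @seealso [weighted_loglik()], [posterior()], [fit_table()]
#' @export
em_fit <- function(data, K, n_starts = 16, max_iter = 1000, tol = 1e-8,
                   seed = 1L, prob_floor = 1e-6, ic_n = "total") {
  stopifnot(inherits(data, "lc_data"))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  n <- nrow(data$responses)
  w <- data$weights
  if (sum(w) <= 0) stop("sum of weights must be positive", call. = FALSE)

  n_pat <- nrow(unique(data$responses[w > 0, , drop = FALSE]))
  if (K > n_pat) {
    warning("K = ", K, " exceeds the ", n_pat,
            " distinct observed response patterns; boundary solutions likely")
  }
  p_count <- n_parameters(K, data$n_categories)

  if (K == 1L) {
    # one-class MLE in closed form: weighted marginal category proportions
    rp <- lapply(seq_along(data$n_categories), function(j) {
      cnt <- vapply(seq_len(data$n_categories[j]), function(cc) {
        sum(w[data$responses[, j] == cc])
      }, numeric(1))
      pr <- cnt / sum(cnt)
      pr <- pmax(pr, prob_floor)
      matrix(pr / sum(pr), nrow = 1)
    })
    params <- lc_params(1, rp)
    ll <- weighted_loglik(data, params)
    return(new_fit_result(params, ll, p_count, w, n, matrix(1, n, 1),
                          TRUE, 0L, 1L, as.integer(seed), "indicator", ic_n))
  }

  start_seeds <- derive_seeds(seed, n_starts)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- em_single_start(data, K, max_iter, tol, start_seeds[s], prob_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    warning("EM did not converge in ", max_iter,
            " iterations for the best of ", n_starts, " starts (K = ", K, ")")
  }
  new_fit_result(best$params, best$loglik, p_count, w, n, best$posteriors,
                 best$converged, best$n_iterations, n_starts,
                 as.integer(seed), "indicator", ic_n)
}

# deterministic start-specific seeds from one master seed
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

# one EM run from a random soft assignment
em_single_start <- function(data, K, max_iter, tol, start_seed, prob_floor) {
  n <- nrow(data$responses)
  w <- data$weights
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(start_seed)
  post <- matrix(stats::runif(n * K, min = 0.05), n, K)
  if (!is.null(old)) assign(".Random.seed", envir = globalenv(), old)
  post <- post / rowSums(post)

  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  params <- NULL
  repeat {
    iter <- iter + 1L
    params <- m_step(data, post, prob_floor)
    e <- e_step(data, params)
    post <- e$posteriors
    ll <- sum((w * e$case_loglik)[w > 0])
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    if (iter >= max_iter) break
  }
  list(params = params, loglik = ll_old, posteriors = post,
       converged = converged, n_iterations = iter)
}

# log pi_k + sum_j log theta_jk(y_ij), N x K
class_case_loglik <- function(data, params) {
  n <- nrow(data$responses)
  K <- params$n_classes
  lp <- matrix(log(params$proportions), n, K, byrow = TRUE)
  for (j in seq_along(params$response_probs)) {
    th <- params$response_probs[[j]]
    if (ncol(th) != data$n_categories[j]) {
      stop("parameter/item dimension mismatch at item ", j, call. = FALSE)
    }
    lp <- lp + t(log(th)[, data$responses[, j], drop = FALSE])
  }
  lp
}

# fast rowwise maximum (apply(m, 1, max) dominates EM cost otherwise)
row_maxs <- function(m) {
  mx <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, j])
  mx
}

e_step <- function(data, params) {
  lp <- class_case_loglik(data, params)
  mx <- row_maxs(lp)
  pz <- exp(lp - mx)
  den <- rowSums(pz)
  list(posteriors = pz / den, case_loglik = mx + log(den))
}

m_step <- function(data, post, prob_floor) {
  w <- data$weights
  wp <- post * w                       # N x K weighted responsibilities
  ck <- colSums(wp)
  proportions <- ck / sum(ck)
  rp <- lapply(seq_along(data$n_categories), function(j) {
    cj <- data$n_categories[j]
    m <- matrix(0, ncol(post), cj)
    y <- data$responses[, j]
    for (cc in seq_len(cj)) m[, cc] <- colSums(wp[y == cc, , drop = FALSE])
    m <- m / rowSums(m)
    m <- pmax(m, prob_floor)
    m / rowSums(m)
  })
  lc_params(proportions, rp)
}

#' Weighted log-likelihood of a latent class model
#'
#' Evaluates \eqn{\sum_i w_i \log \sum_k \pi_k \prod_j \theta_{jk}(y_{ij})}.
#' Cases with zero weight contribute nothing (even if the model assigns
#' them probability zero); a positive-weight case with zero model
#' probability is an error rather than a silent `-Inf`.
#'
#' @param data an [lc_data] object
#' @param params an [lc_params] object, dimensionally consistent with `data`
#' @return the weighted log-likelihood (a scalar)
#' @export
weighted_loglik <- function(data, params) {
  stopifnot(inherits(data, "lc_data"), inherits(params, "lc_params"))
  check_dims(data, params)
  w <- data$weights
  if (all(w == 0)) return(0)
  lp <- class_case_loglik(data, params)
  mx <- row_maxs(lp)
  cl <- mx + log(rowSums(exp(lp - mx)))
  if (any(!is.finite(cl[w > 0]))) {
    stop("a case with positive weight has zero probability under the model",
         call. = FALSE)
  }
  sum((w * cl)[w > 0])
}

check_dims <- function(data, params) {
  if (length(params$response_probs) != ncol(data$responses)) {
    stop("model has ", length(params$response_probs),
         " items but data has ", ncol(data$responses), call. = FALSE)
  }
  for (j in seq_along(params$response_probs)) {
    if (ncol(params$response_probs[[j]]) != data$n_categories[j]) {
      stop("item ", j, ": model has ", ncol(params$response_probs[[j]]),
           " categories but data declares ", data$n_categories[j],
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Posterior class membership probabilities
#'
#' Bayes-rule posteriors
#' \eqn{P(X = k \mid y_i) = \pi_k \prod_j \theta_{jk}(y_{ij}) / P(y_i)};
#' each row sums to 1. During tree growing these posteriors, multiplied by
#' the parent-node weights, become the child-node weights (proportional
#' assignment).
#'
#' @inheritParams weighted_loglik
#' @return N x K matrix of posterior probabilities
#' @export
posterior <- function(data, params) {
  stopifnot(inherits(data, "lc_data"), inherits(params, "lc_params"))
  check_dims(data, params)
  lp <- class_case_loglik(data, params)
  mx <- row_maxs(lp)
  if (any(!is.finite(mx))) {
    stop("a case has zero probability under every class", call. = FALSE)
  }
  pz <- exp(lp - mx)
  pz / rowSums(pz)
}

#' Number of free parameters of a latent class model
#'
#' `(K - 1)` class proportions plus, per item, `K * (C_j - 1)` conditional
#' response probabilities.
#'
#' @param K number of classes
#' @param n_categories per-item category counts
#' @return integer parameter count
#' @examples
#' n_parameters(2, rep(2, 18)) # 37
#' @export
n_parameters <- function(K, n_categories) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  as.integer((K - 1L) + K * sum(as.integer(n_categories) - 1L))
}

#' Information criteria from a log-likelihood
#'
#' `BIC = -2 logL + log(n) P` and `AIC = -2 logL + 2 P`.
#'
#' @param loglik log-likelihood value
#' @param n_params number of free parameters P
#' @param n sample size used in the BIC penalty
#' @return list with elements `bic` and `aic`
#' @examples
#' information_criteria(-94204, 18, 14527)
#' @export
information_criteria <- function(loglik, n_params, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  list(bic = -2 * loglik + log(n) * n_params,
       aic = -2 * loglik + 2 * n_params)
}
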