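#' Construct a top-2 ranking dataset
#'
#' Per case and item, respondents pick a first and a (different) second
#' choice among the item's alternatives.
#'
#' @param first N x J integer matrix of first choices, codes in `1..A_j`
#' @param second N x J integer matrix of second choices, `second != first`
#'   elementwise
#' @param weights length-N nonnegative case weights (default 1)
#' @param n_alternatives per-item alternative counts (default: max
#'   observed code, at least 2)
#' @param item_labels optional item names
#' @return object of class `ranking_data`
#' @export
ranking_data <- function(first, second, weights = NULL,
                         n_alternatives = NULL, item_labels = NULL) {
  first <- as.matrix(first)
  second <- as.matrix(second)
  storage.mode(first) <- "integer"
  storage.mode(second) <- "integer"
  if (!identical(dim(first), dim(second))) {
    stop("first and second choice matrices must have the same shape",
         call. = FALSE)
  }
  if (anyNA(first) || anyNA(second)) {
    stop("missing choices are not supported", call. = FALSE)
  }
  n <- nrow(first)
  j <- ncol(first)
  if (any(first == second)) {
    bad <- which(first == second, arr.ind = TRUE)[1, ]
    stop("first and second choice coincide at row ", bad[1], ", item ",
         bad[2], call. = FALSE)
  }
  if (is.null(n_alternatives)) {
    n_alternatives <- pmax(apply(pmax(first, second), 2, max), 2L)
  }
  n_alternatives <- as.integer(n_alternatives)
  if (length(n_alternatives) != j || any(n_alternatives < 2L)) {
    stop("n_alternatives must give a count >= 2 per item", call. = FALSE)
  }
  rng_ok <- first >= 1L & second >= 1L &
    first <= matrix(n_alternatives, n, j, byrow = TRUE) &
    second <= matrix(n_alternatives, n, j, byrow = TRUE)
  if (!all(rng_ok)) stop("choice codes out of range", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be nonnegative, length N, with positive sum",
         call. = FALSE)
  }
  if (is.null(item_labels)) {
    item_labels <- colnames(first)
    if (is.null(item_labels)) item_labels <- paste0("item", seq_len(j))
  }
  structure(list(first = first, second = second, weights = weights,
                 n_alternatives = n_alternatives,
                 item_labels = as.character(item_labels)),
            class = "ranking_data")
}

#' @export
set_weights.ranking_data <- function(data, weights) {
  ranking_data(data$first, data$second, weights, data$n_alternatives,
               data$item_labels)
}

#' @export
n_cases.ranking_data <- function(data) nrow(data$first)

#' @export
print.ranking_data <- function(x, ...) {
  cat("Top-2 ranking dataset: ", nrow(x$first), " cases x ",
      ncol(x$first), " items (alternatives: ",
      paste(x$n_alternatives, collapse = " "), ")\n", sep = "")
  invisible(x)
}

#' Construct ranking-model parameters
#'
#' Class proportions plus effects-coded logits \eqn{\beta_{jak}} per item,
#' class and alternative (`sum_a beta = 0` within each item-class); the
#' utilities are \eqn{\tau = e^\beta}, shared between first and second
#' choice.
#'
#' @param proportions length-K class proportions
#' @param beta list of J matrices, each K x A_j, rows summing to 0
#' @return object of class `ranking_params`
#' @export
ranking_params <- function(proportions, beta) {
  proportions <- as.numeric(proportions)
  k <- length(proportions)
  if (any(proportions <= 0) || abs(sum(proportions) - 1) > 1e-8) {
    stop("class proportions must be positive and sum to 1", call. = FALSE)
  }
  if (!is.list(beta)) beta <- list(beta)
  for (j in seq_along(beta)) {
    m <- as.matrix(beta[[j]])
    if (nrow(m) != k) stop("beta[[", j, "]] needs one row per class", call. = FALSE)
    if (any(abs(rowSums(m)) > 1e-6)) {
      stop("effects coding violated: rows of beta[[", j,
           "]] must sum to 0", call. = FALSE)
    }
    beta[[j]] <- m
  }
  structure(list(n_classes = k, proportions = proportions, beta = beta),
            class = "ranking_params")
}

#' First/second choice probability under class utilities
#'
#' \deqn{P(a_1, a_2) = \frac{\tau_{a_1}}{\sum_a \tau_a} \cdot
#'   \frac{\tau_{a_2}}{\sum_{a \ne a_1} \tau_a},}
#' with \eqn{\tau_a = e^{\beta_a}}: the first choice is a standard logit
#' over all alternatives and the second choice a logit over the
#' non-selected ones (top-2 exploded logit).
#'
#' @param beta_jk length-A vector of logits for one item and class
#' @param a1,a2 first and second chosen alternatives, `a1 != a2`
#' @return the probability of the ordered pair
#' @examples
#' pair_prob(c(0, 0, 0, 0), 1, 2) # 1/12
#' @export
pair_prob <- function(beta_jk, a1, a2) {
  if (a1 == a2) stop("first and second choice must differ", call. = FALSE)
  tau <- exp(beta_jk - max(beta_jk))
  (tau[a1] / sum(tau)) * (tau[a2] / sum(tau[-a1]))
}

# N x K matrix of log pair-probabilities summed over items, plus log pi
ranking_class_loglik <- function(data, params) {
  n <- nrow(data$first)
  K <- params$n_classes
  lp <- matrix(log(params$proportions), n, K, byrow = TRUE)
  for (j in seq_along(params$beta)) {
    A <- data$n_alternatives[j]
    b <- params$beta[[j]]          # K x A
    lt <- b - apply(b, 1, max)
    tau <- exp(lt)
    log_den1 <- log(rowSums(tau))              # K
    # log denominator of the second choice depends on the removed a1
    log_den2 <- matrix(vapply(seq_len(A), function(a1) {
      log(rowSums(tau[, -a1, drop = FALSE]))
    }, numeric(K)), nrow = K)                   # K x A (column = removed a1)
    a1 <- data$first[, j]
    a2 <- data$second[, j]
    lp <- lp + t(lt)[a1, , drop = FALSE] - matrix(log_den1, n, K, byrow = TRUE) +
      t(lt)[a2, , drop = FALSE] - t(log_den2)[a1, , drop = FALSE]
  }
  lp
}

#' Weighted log-likelihood of the ranking mixture
#'
#' \eqn{\sum_i w_i \log \sum_k \pi_k \prod_j P(a_{1ij}, a_{2ij} \mid k)},
#' with per-item [pair_prob()] factors and local independence across
#' items within a class.
#'
#' @param data a [ranking_data] object
#' @param params a [ranking_params] object
#' @return scalar weighted log-likelihood
#' @export
ranking_loglik <- function(data, params) {
  stopifnot(inherits(data, "ranking_data"), inherits(params, "ranking_params"))
  if (length(params$beta) != ncol(data$first)) {
    stop("model and data disagree on the number of items", call. = FALSE)
  }
  w <- data$weights
  if (all(w == 0)) return(0)
  lp <- ranking_class_loglik(data, params)
  mx <- row_maxs(lp)
  cl <- mx + log(rowSums(exp(lp - mx)))
  if (any(!is.finite(cl[w > 0]))) {
    stop("a case with positive weight has zero probability under the model",
         call. = FALSE)
  }
  sum((w * cl)[w > 0])
}

#' Fit a latent class top-2 ranking model
#'
#' EM for the mixture of top-2 exploded-logit models: the E-step computes
#' posterior class memberships; the M-step updates the class proportions
#' in closed form and maximizes each class-item's weighted choice
#' log-likelihood over its free logits by BFGS with an analytic gradient
#' (effects coding is enforced by construction: A_j - 1 free logits, the
#' last equal to minus their sum). Parameter count is
#' `(K - 1) + K * sum(A_j - 1)`.
#'
#' @param data a [ranking_data] object
#' @param K number of classes
#' @param n_starts,max_iter,tol,seed,ic_n as in [em_fit()]
#' @param inner_tol convergence tolerance of the inner M-step optimizer
#' @return an `lc_fit` object (with `params` a [ranking_params])
#' @export
fit_ranking_lc <- function(data, K, n_starts = 16, max_iter = 500,
                           tol = 1e-8, seed = 1L, inner_tol = 1e-9,
                           ic_n = "total") {
  stopifnot(inherits(data, "ranking_data"))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  n <- nrow(data$first)
  w <- data$weights
  p_count <- as.integer((K - 1L) + K * sum(data$n_alternatives - 1L))

  if (K == 1L) {
    beta <- lapply(seq_along(data$n_alternatives), function(j) {
      matrix(fit_item_logits(pair_counts(data, j, w),
                             data$n_alternatives[j], inner_tol), nrow = 1)
    })
    params <- ranking_params(1, beta)
    ll <- ranking_loglik(data, params)
    return(new_fit_result(params, ll, p_count, w, n, matrix(1, n, 1),
                          TRUE, 0L, 1L, as.integer(seed), "ranking", ic_n))
  }

  start_seeds <- derive_seeds(seed, n_starts)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- ranking_em_start(data, K, max_iter, tol, start_seeds[s], inner_tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    warning("ranking EM did not converge in ", max_iter,
            " iterations (best of ", n_starts, " starts, K = ", K, ")")
  }
  new_fit_result(best$params, best$loglik, p_count, w, n, best$posteriors,
                 best$converged, best$n_iterations, n_starts,
                 as.integer(seed), "ranking", ic_n)
}

# aggregate weighted counts over the A*(A-1) observed ordered pairs
pair_counts <- function(data, j, wk) {
  A <- data$n_alternatives[j]
  idx <- (data$first[, j] - 1L) * A + data$second[, j]
  cnt <- numeric(A * A)
  agg <- tapply(wk, idx, sum)
  cnt[as.integer(names(agg))] <- agg
  matrix(cnt, A, A)  # [a2, a1] weighted counts
}

# weighted ML of one item-class's logits from its pair-count matrix,
# free parameterization beta = (b_1..b_{A-1}, -sum b); concave objective
fit_item_logits <- function(counts, A, inner_tol) {
  nw <- sum(counts)
  if (nw <= 0) return(rep(0, A))
  n1 <- colSums(counts)   # first-choice counts per a1
  negll <- function(free) {
    b <- c(free, -sum(free))
    tau <- exp(b - max(b))
    ld1 <- log(sum(tau))
    val <- 0
    for (a1 in seq_len(A)) {
      if (n1[a1] == 0 && all(counts[, a1] == 0)) next
      ld2 <- log(sum(tau[-a1]))
      sec <- counts[, a1]
      val <- val + n1[a1] * (b[a1] - max(b) - ld1) +
        sum(sec * (b - max(b) - ld2)) - sec[a1] * (b[a1] - max(b) - ld2)
    }
    -val
  }
  grad <- function(free) {
    b <- c(free, -sum(free))
    tau <- exp(b - max(b))
    p1 <- tau / sum(tau)
    g <- n1 - nw * p1                     # first-choice score
    for (a1 in seq_len(A)) {
      sec <- counts[, a1]
      m <- sum(sec)
      if (m == 0) next
      q <- tau
      q[a1] <- 0
      q <- q / sum(q)
      g <- g + sec - m * q                # second-choice score given a1
    }
    gf <- g[seq_len(A - 1L)] - g[A]       # chain rule for b_A = -sum(free)
    -gf
  }
  opt <- stats::optim(rep(0, A - 1L), negll, grad, method = "BFGS",
                      control = list(reltol = inner_tol, maxit = 200))
  b <- c(opt$par, -sum(opt$par))
  b - mean(b)  # numerically exact effects coding
}

ranking_em_start <- function(data, K, max_iter, tol, start_seed, inner_tol) {
  n <- nrow(data$first)
  J <- ncol(data$first)
  w <- data$weights
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(start_seed)
  post <- matrix(stats::runif(n * K, min = 0.05), n, K)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  post <- post / rowSums(post)

  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  params <- NULL
  repeat {
    iter <- iter + 1L
    # M-step
    wp <- post * w
    ck <- colSums(wp)
    proportions <- ck / sum(ck)
    beta <- lapply(seq_len(J), function(j) {
      t(vapply(seq_len(K), function(k) {
        fit_item_logits(pair_counts(data, j, wp[, k]),
                        data$n_alternatives[j], inner_tol)
      }, numeric(data$n_alternatives[j])))
    })
    params <- ranking_params(proportions, beta)
    # E-step
    lp <- ranking_class_loglik(data, params)
    mx <- row_maxs(lp)
    pz <- exp(lp - mx)
    den <- rowSums(pz)
    post <- pz / den
    ll <- sum((w * (mx + log(den)))[w > 0])
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
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
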