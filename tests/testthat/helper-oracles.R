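# Independent oracles, written without reuse of the package's internal
# computation paths: plain loops and enumeration only.

# mixture log-likelihood by explicit enumeration of every class term
brute_force_loglik <- function(data, params) {
  total <- 0
  for (i in seq_len(nrow(data$responses))) {
    if (data$weights[i] == 0) next
    p_i <- 0
    for (k in seq_len(params$n_classes)) {
      term <- params$proportions[k]
      for (j in seq_len(ncol(data$responses))) {
        term <- term * params$response_probs[[j]][k, data$responses[i, j]]
      }
      p_i <- p_i + term
    }
    total <- total + data$weights[i] * log(p_i)
  }
  total
}

# mixture loglik of a 2-class binary-item model at one parameter point
# theta: vector (pi1, p_11..p_1J, p_21..p_2J), p = P(code 1)
eval_k2_binary <- function(theta, responses, weights) {
  J <- ncol(responses)
  pi1 <- theta[1]
  p1 <- theta[1 + seq_len(J)]
  p2 <- theta[1 + J + seq_len(J)]
  ll <- 0
  for (i in seq_len(nrow(responses))) {
    y <- responses[i, ]
    t1 <- pi1 * prod(ifelse(y == 1, p1, 1 - p1))
    t2 <- (1 - pi1) * prod(ifelse(y == 1, p2, 1 - p2))
    ll <- ll + weights[i] * log(t1 + t2)
  }
  ll
}

# maximum loglik of the 2-class binary-item model: dense grid search
# followed by a Nelder-Mead polish of the best grid point (logit scale)
grid_oracle_k2 <- function(responses, weights, grid_step = 0.1,
                           refine = TRUE) {
  J <- ncol(responses)
  vals <- seq(grid_step / 2, 1 - grid_step / 2, by = grid_step)
  grid <- as.matrix(expand.grid(rep(list(vals), 1 + 2 * J)))
  ll <- numeric(nrow(grid))
  for (i in seq_len(nrow(responses))) {
    if (weights[i] == 0) next
    t1 <- grid[, 1]
    t2 <- 1 - grid[, 1]
    for (j in seq_len(J)) {
      p1 <- grid[, 1 + j]
      p2 <- grid[, 1 + J + j]
      if (responses[i, j] == 1) {
        t1 <- t1 * p1
        t2 <- t2 * p2
      } else {
        t1 <- t1 * (1 - p1)
        t2 <- t2 * (1 - p2)
      }
    }
    ll <- ll + weights[i] * log(t1 + t2)
  }
  best_ll <- max(ll)
  best <- grid[which.max(ll), ]
  if (!refine) return(best_ll)
  to_logit <- function(p) log(p / (1 - p))
  from_logit <- function(x) 1 / (1 + exp(-x))
  obj <- function(x) -eval_k2_binary(from_logit(x), responses, weights)
  opt <- stats::optim(to_logit(best), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  max(best_ll, -opt$value)
}

# ranking mixture loglik by explicit enumeration (independent of
# ranking_class_loglik): per-item pair probability from first principles
brute_force_ranking_loglik <- function(data, params) {
  total <- 0
  for (i in seq_len(nrow(data$first))) {
    if (data$weights[i] == 0) next
    p_i <- 0
    for (k in seq_len(params$n_classes)) {
      term <- params$proportions[k]
      for (j in seq_len(ncol(data$first))) {
        tau <- exp(params$beta[[j]][k, ])
        a1 <- data$first[i, j]
        a2 <- data$second[i, j]
        term <- term * (tau[a1] / sum(tau)) * (tau[a2] / sum(tau[-a1]))
      }
      p_i <- p_i + term
    }
    total <- total + data$weights[i] * log(p_i)
  }
  total
}

# best assignment of fitted classes to true classes by profile distance,
# returns the permutation of fitted classes
match_classes <- function(true_mat, fitted_mat) {
  K <- nrow(true_mat)
  perms <- all_perms(K)
  best <- perms[[1]]
  best_d <- Inf
  for (p in perms) {
    d <- sum(abs(true_mat - fitted_mat[p, , drop = FALSE]))
    if (d < best_d) {
      best_d <- d
      best <- p
    }
  }
  best
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_perms(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[rest])
    }
  }
  out
}

# small deterministic toy dataset used across tests
toy_data <- function() {
  lc_data(rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2), c(1, 1), c(2, 2)),
          weights = c(2, 1, 1, 2, 1, 3))
}
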