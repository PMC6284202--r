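#' Simulate categorical data from a latent class model
#'
#' Draws a class label per case from `class_sizes`, then each item
#' response independently given the class (local independence). Weights
#' are 1. The true class labels are kept in `attr(, "true_class")`.
#'
#' @param n_cases number of cases
#' @param class_sizes class proportions, summing to 1
#' @param profiles either a K x J matrix of success probabilities for
#'   binary items (the probability of category 1), or a list of J
#'   matrices K x C_j of full category probabilities
#' @param seed integer seed
#' @return an [lc_data] object with `attr(, "true_class")`
#' @examples
#' d <- simulate_lc(100, c(.5, .5), rbind(rep(.8, 6), rep(.2, 6)), seed = 1)
#' table(attr(d, "true_class"))
#' @export
simulate_lc <- function(n_cases, class_sizes, profiles, seed = 1L) {
  class_sizes <- as.numeric(class_sizes)
  if (any(class_sizes < 0) || abs(sum(class_sizes) - 1) > 1e-8) {
    stop("class_sizes must be nonnegative and sum to 1", call. = FALSE)
  }
  K <- length(class_sizes)
  if (is.matrix(profiles)) {
    if (any(profiles < 0) || any(profiles > 1)) {
      stop("profile probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (nrow(profiles) != K) stop("profiles must have one row per class", call. = FALSE)
    # category 1 = "positive" response with the profiled probability
    profiles <- lapply(seq_len(ncol(profiles)), function(j) {
      cbind(profiles[, j], 1 - profiles[, j])
    })
  }
  J <- length(profiles)
  for (m in profiles) {
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
      stop("each profile row must be a probability vector summing to 1",
           call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  z <- sample.int(K, n_cases, replace = TRUE, prob = class_sizes)
  y <- matrix(0L, n_cases, J)
  for (j in seq_len(J)) {
    cj <- ncol(profiles[[j]])
    u <- stats::runif(n_cases)
    cum <- matrix(t(apply(profiles[[j]], 1, cumsum)), nrow = K)  # K x C_j
    # invert the per-case cdf: code = 1 + number of cumulative bounds below u
    y[, j] <- vapply(seq_len(n_cases), function(i) {
      min(1L + sum(u[i] > cum[z[i], ]), cj)
    }, integer(1))
  }
  d <- lc_data(y, n_categories = vapply(profiles, ncol, integer(1)))
  attr(d, "true_class") <- z
  d
}

#' Benchmark class configurations for the root-split simulation study
#'
#' Three built-in class layouts on 10 binary items with equal class
#' sizes, emulating the canonical situations for sizing the first split
#' of a latent class tree:
#' \describe{
#'   \item{A}{three classes: one distinct class (response probability 0.8
#'     throughout) and two fairly similar classes whose item probabilities
#'     average 0.2 (0.3/0.1 on complementary halves of the items), so the
#'     first binary split isolates class 1 and the next split still
#'     separates classes 2 and 3. Binary splits suffice.}
#'   \item{B}{three mutually distinct classes (0.8 throughout; 0.2
#'     throughout; 0.8 on items 1-5 and 0.2 on items 6-10). A ternary
#'     root split is appropriate.}
#'   \item{C}{four classes in two macro-clusters: classes 1-2 average
#'     response probability 0.8 and differ (0.975 vs 0.625) on items 1-5
#'     only; classes 3-4 average 0.2 and differ (0.375 vs 0.025) on the
#'     disjoint item subset 6-10. The first binary split separates the
#'     macro-clusters and two further binary splits recover all four
#'     classes.}
#' }
#' The exact probability values are fixed package constants; the study
#' conclusions depend on the qualitative separation structure, not on the
#' precise values.
#'
#' @param name `"A"`, `"B"` or `"C"`
#' @return a list of class `lct_sim_config` with elements `name`,
#'   `n_cases` (1000), `class_sizes` (equal), `profiles` (K x 10 matrix of
#'   success probabilities)
#' @export
config_profiles <- function(name = c("A", "B", "C")) {
  name <- match.arg(name)
  lo5 <- function(a, b) c(rep(a, 5), rep(b, 5))
  profiles <- switch(name,
    A = rbind(rep(0.8, 10),
              lo5(0.3, 0.1),
              lo5(0.1, 0.3)),
    B = rbind(rep(0.8, 10),
              rep(0.2, 10),
              lo5(0.8, 0.2)),
    C = rbind(lo5(0.975, 0.8),
              lo5(0.625, 0.8),
              lo5(0.2, 0.375),
              lo5(0.2, 0.025)))
  K <- nrow(profiles)
  structure(list(name = name, n_cases = 1000L,
                 class_sizes = rep(1 / K, K), profiles = profiles),
            class = "lct_sim_config")
}

#' @export
print.lct_sim_config <- function(x, ...) {
  cat("Simulation configuration", x$name, ":", nrow(x$profiles),
      "equal-sized classes,", ncol(x$profiles), "binary items, n =",
      x$n_cases, "\n")
  print(round(x$profiles, 2))
  invisible(x)
}

#' Simulate top-2 ranking (first/second choice) data
#'
#' Draws a class from the class proportions, then per item a first choice
#' with probability proportional to the class utilities
#' \eqn{\tau_a = e^{\beta_a}} and a second choice proportional to the
#' utilities of the remaining alternatives.
#'
#' @param params a [ranking_params] object
#' @param n number of cases
#' @param seed integer seed
#' @return a [ranking_data] object with `attr(, "true_class")`
#' @export
simulate_ranking <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "ranking_params"))
  set.seed(as.integer(seed))
  K <- params$n_classes
  J <- length(params$beta)
  z <- sample.int(K, n, replace = TRUE, prob = params$proportions)
  first <- matrix(0L, n, J)
  second <- matrix(0L, n, J)
  for (j in seq_len(J)) {
    tau <- exp(params$beta[[j]])   # K x A
    A <- ncol(tau)
    for (i in seq_len(n)) {
      t_i <- tau[z[i], ]
      a1 <- sample.int(A, 1, prob = t_i)
      t2 <- t_i
      t2[a1] <- 0
      a2 <- sample.int(A, 1, prob = t2)
      first[i, j] <- a1
      second[i, j] <- a2
    }
  }
  d <- ranking_data(first, second,
                    n_alternatives = vapply(params$beta, ncol, integer(1)))
  attr(d, "true_class") <- z
  d
}

#' Simulation study of the relative-improvement measure
#'
#' For each replication: simulate a dataset from the given configuration,
#' fit 1..Kmax-class models, and record the relative improvements
#' \eqn{RI_{2,3}} (and \eqn{RI_{3,4}} when Kmax >= 4). Summarizes how the
#' measure behaves under class layouts where binary root splits do and do
#' not suffice.
#'
#' @param config a configuration name (`"A"`, `"B"`, `"C"`) or an
#'   `lct_sim_config`
#' @param n_replications number of simulated datasets (default 20; the
#'   full-scale study uses 100)
#' @param Kmax largest class count fitted per replication (default 4)
#' @param seed master seed; replication seeds are derived from it
#' @param n_starts EM starts per fit
#' @param ... further options passed to [em_fit()]
#' @return an object of class `lct_ri_study`: a data.frame with one row
#'   per replication (`rep`, `ri_23`, optionally `ri_34`, `all_converged`),
#'   with the configuration in attributes
#' @examples
#' \donttest{
#' st <- run_ri_study("B", n_replications = 3, Kmax = 3, seed = 1, n_starts = 4)
#' summary(st$ri_23)
#' }
#' @export
run_ri_study <- function(config, n_replications = 20, Kmax = 4, seed = 1L,
                         n_starts = 16, ...) {
  if (is.character(config)) config <- config_profiles(config)
  stopifnot(inherits(config, "lct_sim_config"))
  if (Kmax < 3L) stop("Kmax must be >= 3 to measure RI_{2,3}", call. = FALSE)
  rep_seeds <- derive_seeds(seed, n_replications)
  rows <- lapply(seq_len(n_replications), function(r) {
    d <- simulate_lc(config$n_cases, config$class_sizes, config$profiles,
                     seed = rep_seeds[r])
    ft <- fit_table(d, Kmax = Kmax, seed = rep_seeds[r],
                    n_starts = n_starts, ...)
    ri <- relative_improvement(ft, "loglik")
    out <- data.frame(rep = r, ri_23 = ri$ri[ri$K == 2L],
                      all_converged = all(ft$converged))
    if (Kmax >= 4L) out$ri_34 <- ri$ri[ri$K == 3L]
    out
  })
  res <- do.call(rbind, rows)
  if (!all(res$all_converged)) {
    warning(sum(!res$all_converged),
            " replication(s) contained a nonconverged fit")
  }
  structure(res, config = config, seed = seed,
            class = c("lct_ri_study", "data.frame"))
}

#' @export
print.lct_ri_study <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("RI study, configuration ", cfg$name, ": ", nrow(x),
      " replications of n = ", cfg$n_cases, "\n", sep = "")
  cat("  RI_{2,3}: median ", round(stats::median(x$ri_23), 3),
      ", range [", round(min(x$ri_23), 3), ", ", round(max(x$ri_23), 3),
      "]\n", sep = "")
  if (!is.null(x$ri_34)) {
    cat("  RI_{3,4}: median ", round(stats::median(x$ri_34), 3), "\n", sep = "")
  }
  invisible(x)
}

#' Write per-replication RI study values to CSV
#' @param study an `lct_ri_study`
#' @param path output file path
#' @return the path, invisibly
#' @export
write_ri_study <- function(study, path) {
  utils::write.csv(as.data.frame(study), path, row.names = FALSE)
  invisible(path)
}
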