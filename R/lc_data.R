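#' Construct a categorical dataset for latent class analysis
#'
#' Bundles an N x J matrix of integer-coded categorical responses with
#' per-case weights. Codes for item j must lie in `1..n_categories[j]`.
#' Weights default to 1 (the unweighted root-node case); during tree
#' growing they carry posterior membership probabilities (proportional
#' assignment).
#'
#' @param responses integer matrix (or data.frame coercible to one),
#'   N cases by J items, codes starting at 1. Missing values are rejected.
#' @param weights numeric vector of length N, all >= 0, at least one > 0.
#'   Default: unit weights.
#' @param item_labels character vector of length J; defaults to column
#'   names or `V1..VJ`.
#' @param n_categories integer vector of per-item category counts
#'   (each >= 2); defaults to the per-column maximum observed code.
#' @return An object of class `lc_data`: a list with elements
#'   `responses`, `weights`, `item_labels`, `n_categories`.
#' @examples
#' d <- lc_data(matrix(c(1, 2, 2, 1), 2, 2))
#' d$n_categories
#' @export
lc_data <- function(responses, weights = NULL, item_labels = NULL,
                    n_categories = NULL) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (!is.matrix(responses)) responses <- matrix(responses, nrow = length(responses))
  if (anyNA(responses)) {
    bad <- which(is.na(responses), arr.ind = TRUE)[1, ]
    stop("missing response at row ", bad[1], ", column ", bad[2],
         "; missing data are not supported", call. = FALSE)
  }
  storage.mode(responses) <- "integer"
  n <- nrow(responses)
  j <- ncol(responses)
  if (n < 1L || j < 1L) stop("need at least one case and one item", call. = FALSE)
  if (any(responses < 1L)) stop("response codes must be >= 1", call. = FALSE)
  if (is.null(n_categories)) {
    n_categories <- pmax(apply(responses, 2, max), 2L)
  }
  n_categories <- as.integer(n_categories)
  if (length(n_categories) != j || any(n_categories < 2L)) {
    stop("n_categories must give a count >= 2 for each of the ", j, " items",
         call. = FALSE)
  }
  over <- responses > matrix(n_categories, n, j, byrow = TRUE)
  if (any(over)) {
    bad <- which(over, arr.ind = TRUE)[1, ]
    stop("response code ", responses[bad[1], bad[2]], " at row ", bad[1],
         ", column ", bad[2], " exceeds its item's category count", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  if (length(weights) != n) stop("weights must have length N = ", n, call. = FALSE)
  if (anyNA(weights) || any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  # an all-zero weight vector is representable (empty weighted sum);
  # estimation functions reject it
  if (is.null(item_labels)) {
    item_labels <- colnames(responses)
    if (is.null(item_labels)) item_labels <- paste0("V", seq_len(j))
  }
  structure(
    list(responses = responses, weights = weights,
         item_labels = as.character(item_labels),
         n_categories = n_categories),
    class = "lc_data")
}

#' @export
print.lc_data <- function(x, ...) {
  cat("Categorical dataset: ", nrow(x$responses), " cases x ",
      ncol(x$responses), " items\n", sep = "")
  cat("  categories per item:", paste(x$n_categories, collapse = " "), "\n")
  cat("  effective size (sum of weights):",
      format(sum(x$weights), digits = 6), "\n")
  invisible(x)
}

#' Replace the case weights of a dataset
#'
#' Used by the tree builder to estimate node-conditional models: every case
#' is carried into every node with its posterior membership weight.
#'
#' @param data an `lc_data` or `ranking_data` object
#' @param weights new nonnegative weight vector of length N
#' @return the dataset with `weights` replaced
#' @export
set_weights <- function(data, weights) UseMethod("set_weights")

#' @export
set_weights.lc_data <- function(data, weights) {
  lc_data(data$responses, weights, data$item_labels, data$n_categories)
}

#' Number of cases in a dataset
#' @param data an `lc_data` or `ranking_data` object
#' @return integer case count
#' @export
n_cases <- function(data) UseMethod("n_cases")

#' @export
n_cases.lc_data <- function(data) nrow(data$responses)

#' Construct a latent class parameter set
#'
#' Class proportions \eqn{\pi_k} and class-conditional response
#' probabilities \eqn{P(y_j = c \mid X = k)} for a K-class model under
#' local independence.
#'
#' @param proportions length-K vector, positive, summing to 1
#' @param response_probs list of J matrices; matrix j is K x C_j with rows
#'   summing to 1
#' @return object of class `lc_params`
#' @examples
#' p <- lc_params(c(.4, .6), list(rbind(c(.9, .1), c(.2, .8))))
#' @export
lc_params <- function(proportions, response_probs) {
  proportions <- as.numeric(proportions)
  k <- length(proportions)
  if (k < 1L) stop("need at least one class", call. = FALSE)
  if (any(proportions <= 0) || abs(sum(proportions) - 1) > 1e-8) {
    stop("class proportions must be positive and sum to 1", call. = FALSE)
  }
  if (!is.list(response_probs)) response_probs <- list(response_probs)
  for (j in seq_along(response_probs)) {
    m <- as.matrix(response_probs[[j]])
    if (nrow(m) != k) {
      stop("response_probs[[", j, "]] must have one row per class", call. = FALSE)
    }
    if (any(m < 0) || any(m > 1) || any(abs(rowSums(m) - 1) > 1e-8)) {
      stop("rows of response_probs[[", j, "]] must be probabilities summing to 1",
           call. = FALSE)
    }
    response_probs[[j]] <- m
  }
  structure(list(n_classes = k, proportions = proportions,
                 response_probs = response_probs),
            class = "lc_params")
}

#' @export
print.lc_params <- function(x, digits = 3, ...) {
  cat("Latent class parameters:", x$n_classes, "classes,",
      length(x$response_probs), "items\n")
  cat("  proportions:", paste(round(x$proportions, digits), collapse = " "), "\n")
  invisible(x)
}

# assemble the common fit-result container shared by the indicator and
# ranking estimators
new_fit_result <- function(params, loglik, n_params, data_weights, n_total,
                           posteriors, converged, n_iterations, n_starts_used,
                           seed, model = "indicator", ic_n = "total") {
  n_eff <- sum(data_weights)
  n_ic <- if (identical(ic_n, "effective")) n_eff else n_total
  ic <- information_criteria(loglik, n_params, n_ic)
  structure(
    list(params = params, loglik = loglik, n_params = n_params,
         n_cases_effective = n_eff, n_total = n_total,
         bic = ic$bic, aic = ic$aic, posteriors = posteriors,
         converged = converged, n_iterations = n_iterations,
         n_starts_used = n_starts_used, seed = seed, model = model,
         ic_n = ic_n),
    class = "lc_fit")
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(x$params$n_classes, "-class ", x$model, " model: logL = ",
      format(x$loglik, digits = 8), ", P = ", x$n_params,
      ", BIC = ", format(x$bic, digits = 8),
      ", AIC = ", format(x$aic, digits = 8), "\n", sep = "")
  cat("  converged: ", x$converged, " (", x$n_iterations, " iterations, ",
      x$n_starts_used, " starts, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
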