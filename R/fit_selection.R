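#' Fit latent class models over a range of class counts
#'
#' Estimates models with K = 1..Kmax classes on the same (possibly
#' weighted) data and collects log-likelihood, parameter count, BIC and
#' AIC per row — the table from which the relative-improvement measure
#' and the root-split size are derived.
#'
#' @param data an [lc_data] (or, with the ranking adapter, [ranking_data])
#'   object
#' @param Kmax largest number of classes to fit (>= 2)
#' @param adapter model adapter, [lc_adapter()] (default) or
#'   [ranking_adapter()]
#' @param seed master seed, passed to every fit (each K fits from the same
#'   derived start seeds, so the table is reproducible)
#' @param ... further options passed to the adapter's fit function
#'   (`n_starts`, `max_iter`, `tol`, ...)
#' @return an object of class `lct_fit_table`: a data.frame with columns
#'   `K`, `loglik`, `n_params`, `bic`, `aic`, `converged`, with the fitted
#'   models in `attr(, "fits")` and the sample size in `attr(, "n_total")`
#' @examples
#' d <- simulate_lc(300, c(.5, .5), rbind(rep(.9, 5), rep(.1, 5)), seed = 7)
#' ft <- fit_table(d, Kmax = 3, n_starts = 4, seed = 7)
#' relative_improvement(ft)
#' @export
fit_table <- function(data, Kmax, adapter = lc_adapter(), seed = 1L, ...) {
  Kmax <- as.integer(Kmax)
  if (Kmax < 2L) {
    stop("Kmax must be >= 2: the relative-improvement measure needs at ",
         "least the 1- and 2-class baseline", call. = FALSE)
  }
  fits <- lapply(seq_len(Kmax), function(k) adapter$fit(data, k, seed = seed, ...))
  tab <- data.frame(
    K = seq_len(Kmax),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_params = vapply(fits, `[[`, integer(1), "n_params"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  if (any(diff(tab$loglik) < -1e-6)) {
    warning("log-likelihood decreased when adding a class; ",
            "some fits likely hit local optima — consider more starts")
  }
  structure(tab, fits = fits, n_total = fits[[1]]$n_total,
            class = c("lct_fit_table", "data.frame"))
}

#' Assemble a fit table from precomputed statistics
#'
#' Builds the container [relative_improvement()] and [select_root_size()]
#' operate on from already-available fit statistics (e.g. a published fit
#' table), without refitting anything. Measures not supplied are left `NA`.
#'
#' @param K vector of class counts, consecutive from 1
#' @param loglik,bic,aic per-K fit measures (any subset)
#' @param n_params per-K parameter counts (optional)
#' @param n_total sample size (optional, for display)
#' @return an `lct_fit_table`
#' @examples
#' ft <- as_fit_table(K = 1:3, loglik = c(-94204, -89510, -88501))
#' relative_improvement(ft)$ri
#' @export
as_fit_table <- function(K, loglik = NULL, bic = NULL, aic = NULL,
                         n_params = NULL, n_total = NA_integer_) {
  K <- as.integer(K)
  if (!identical(K, seq_len(length(K))) || length(K) < 2L) {
    stop("K must be the consecutive sequence 1..Kmax", call. = FALSE)
  }
  pick <- function(x) if (is.null(x)) rep(NA_real_, length(K)) else as.numeric(x)
  tab <- data.frame(K = K, loglik = pick(loglik),
                    n_params = if (is.null(n_params)) NA_integer_ else as.integer(n_params),
                    bic = pick(bic), aic = pick(aic), converged = NA)
  structure(tab, fits = NULL, n_total = n_total,
            class = c("lct_fit_table", "data.frame"))
}

#' Relative improvement of fit between successive class counts
#'
#' The gain in fit from K to K+1 classes relative to the gain from 1 to 2
#' classes:
#' \deqn{RI_{K,K+1} = \frac{logL_{K+1} - logL_K}{logL_2 - logL_1}.}
#' For BIC or AIC the improvement is the *decrease*,
#' \eqn{(m_K - m_{K+1}) / (m_1 - m_2)}. `RI_{1,2} = 1` by construction and
#' is included as a sanity row. A small value indicates that a K-class
#' model suffices as the first (root) split of a latent class tree.
#'
#' @param fit_table an `lct_fit_table` from [fit_table()] or [as_fit_table()]
#' @param measure which fit measure to take the improvement of:
#'   `"loglik"` (default), `"bic"` or `"aic"`
#' @return an object of class `lct_ri_table`: a data.frame with columns
#'   `K`, `K_next` and `ri`, where row K holds \eqn{RI_{K,K+1}}
#' @export
relative_improvement <- function(fit_table,
                                 measure = c("loglik", "bic", "aic")) {
  measure <- match.arg(measure)
  stopifnot(inherits(fit_table, "lct_fit_table"))
  m <- fit_table[[measure]]
  if (anyNA(m)) stop("fit table has no '", measure, "' column values", call. = FALSE)
  sgn <- if (measure == "loglik") 1 else -1  # for bic/aic improvement = decrease
  gain <- sgn * diff(m)
  denom <- gain[1]
  if (!is.finite(denom) || denom <= 0) {
    stop("the 1- to 2-class improvement in ", measure,
         " is not positive; the relative-improvement measure is undefined",
         call. = FALSE)
  }
  ri <- gain / denom
  if (any(ri > 1 + 1e-12)) {
    warning("relative improvement exceeds 1 for some K (measure '", measure,
            "'): a later split improves fit more than the first; reported as is")
  }
  structure(
    data.frame(K = seq_along(ri), K_next = seq_along(ri) + 1L, ri = ri),
    measure = measure, class = c("lct_ri_table", "data.frame"))
}

#' Select the root-split size from a relative-improvement table
#'
#' Returns the smallest K >= 2 whose relative improvement when moving to
#' K+1 classes falls below `threshold`: beyond K classes, adding a class
#' buys little fit compared with the first split, so the root of the tree
#' is given K child classes.
#'
#' @param ri_table an `lct_ri_table` from [relative_improvement()]
#' @param threshold cutoff on RI, in (0, 1); default 0.10
#' @return integer root size; if no K qualifies, the largest fitted K is
#'   returned with a warning
#' @examples
#' ft <- as_fit_table(1:4, loglik = c(-94204, -89510, -88501, -88117))
#' select_root_size(relative_improvement(ft))
#' @export
select_root_size <- function(ri_table, threshold = 0.10) {
  stopifnot(inherits(ri_table, "lct_ri_table"))
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  cand <- ri_table$K[ri_table$K >= 2L & ri_table$ri < threshold]
  if (length(cand) == 0L) {
    kmax <- max(ri_table$K_next)
    warning("no K has relative improvement below ", threshold,
            "; returning the largest fitted size ", kmax)
    return(as.integer(kmax))
  }
  as.integer(min(cand))
}

#' Format a fit table with its relative-improvement columns for display
#'
#' Lays out the table in the conventional form: one row per K with
#' integer-rounded BIC/AIC and three-decimal RLL/RBIC/RAIC columns, where
#' the RI printed at row K is the improvement from K-1 to K classes.
#'
#' @param fit_table an `lct_fit_table`
#' @param digits decimals for the RI columns (default 3)
#' @return a data.frame with columns `K`, `logL`, `P`, `BIC`, `AIC`,
#'   `RLL`, `RBIC`, `RAIC` (RI columns `NA` where the measure is missing)
#' @export
format_fit_table <- function(fit_table, digits = 3) {
  stopifnot(inherits(fit_table, "lct_fit_table"))
  kmax <- max(fit_table$K)
  ri_col <- function(measure) {
    out <- rep(NA_real_, kmax)
    if (!anyNA(fit_table[[measure]])) {
      ri <- relative_improvement(fit_table, measure)
      out[ri$K_next] <- round(ri$ri, digits)  # row K shows RI_{K-1,K}
    }
    out
  }
  rnd <- function(x) ifelse(is.na(x), NA_real_, round(x))
  data.frame(K = fit_table$K,
             logL = round(fit_table$loglik, 1),
             P = fit_table$n_params,
             BIC = rnd(fit_table$bic),
             AIC = rnd(fit_table$aic),
             RLL = suppressWarnings(ri_col("loglik")),
             RBIC = suppressWarnings(ri_col("bic")),
             RAIC = suppressWarnings(ri_col("aic")))
}

#' Write a formatted fit/RI table to CSV
#'
#' @param fit_table an `lct_fit_table`
#' @param path output file path
#' @return the path, invisibly
#' @export
write_fit_table <- function(fit_table, path) {
  utils::write.csv(format_fit_table(fit_table), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @export
print.lct_fit_table <- function(x, ...) {
  cat("Latent class fit table (n =", attr(x, "n_total"), ")\n")
  print(format_fit_table(x))
  invisible(x)
}

#' @export
print.lct_ri_table <- function(x, ...) {
  cat("Relative improvement of fit (measure:", attr(x, "measure"), ")\n")
  df <- as.data.frame(x)
  df$ri <- round(df$ri, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
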