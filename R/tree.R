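#' Model adapters for tree growing
#'
#' A model adapter makes [grow_tree()] and [fit_table()] agnostic to the
#' likelihood in use: it exposes `fit(data, K, ...) -> lc_fit` for a
#' dataset carrying its own case weights. `lc_adapter()` wraps the
#' categorical-indicator estimator [em_fit()]; `ranking_adapter()` wraps
#' the top-2 ranking estimator [fit_ranking_lc()].
#'
#' @return a list with elements `name` and `fit`
#' @export
lc_adapter <- function() {
  list(name = "indicator",
       fit = function(data, K, ...) em_fit(data, K, ...))
}

#' @rdname lc_adapter
#' @export
ranking_adapter <- function() {
  list(name = "ranking",
       fit = function(data, K, ...) fit_ranking_lc(data, K, ...))
}

#' Child-node case weights from parent weights and posteriors
#'
#' Proportional assignment: the weight of case i at child k is the parent
#' weight times the posterior probability of the child class given the
#' parent, so a weight at depth d is a product of d posteriors and the
#' per-case sum over children reproduces the parent weight exactly.
#'
#' @param parent_weights length-N nonnegative weights at the parent node
#' @param posteriors N x K posterior matrix (rows summing to 1)
#' @return list of K length-N child weight vectors
#' @export
child_weights <- function(parent_weights, posteriors) {
  posteriors <- as.matrix(posteriors)
  if (length(parent_weights) != nrow(posteriors)) {
    stop("parent_weights and posteriors disagree on the number of cases",
         call. = FALSE)
  }
  lapply(seq_len(ncol(posteriors)), function(k) {
    parent_weights * posteriors[, k]
  })
}

#' Test whether a node should be split
#'
#' Fits a 1-class and a `k_split`-class model on the data reweighted by
#' the node's case weights and accepts the split iff the chosen
#' information criterion of the `k_split`-class model is lower. A node
#' with fewer effective cases than the split model has parameters is
#' auto-rejected.
#'
#' @param node_weights length-N weight vector of the node
#' @param data the root dataset ([lc_data] or [ranking_data])
#' @param criterion `"bic"` (default) or `"aic"`
#' @param k_split number of child classes to test (default 2)
#' @param adapter model adapter (see [lc_adapter()])
#' @param seed seed for the fits
#' @param ic_n BIC sample-size convention, `"total"` or `"effective"`
#'   (see [em_fit()])
#' @param ... further options for the adapter fit
#' @return list with `accepted` (flag), `model` (the `k_split`-class
#'   `lc_fit`), `null_model` (the 1-class fit) and `criterion` values
#' @export
try_split <- function(node_weights, data, criterion = c("bic", "aic"),
                      k_split = 2L, adapter = lc_adapter(), seed = 1L,
                      ic_n = "total", ...) {
  criterion <- match.arg(criterion)
  size <- sum(node_weights)
  if (size <= 0) stop("node has zero size", call. = FALSE)
  wdata <- set_weights(data, node_weights)
  null_model <- adapter$fit(wdata, 1L, seed = seed, ic_n = ic_n, ...)
  split_model <- adapter$fit(wdata, as.integer(k_split), seed = seed,
                             ic_n = ic_n, ...)
  if (size < split_model$n_params) {
    warning("node effective size ", round(size, 1), " is below the ",
            split_model$n_params, " parameters of the ", k_split,
            "-class model; split rejected")
    accepted <- FALSE
  } else {
    accepted <- split_model[[criterion]] < null_model[[criterion]]
  }
  list(accepted = accepted, model = split_model, null_model = null_model,
       criterion = stats::setNames(c(null_model[[criterion]],
                                     split_model[[criterion]]),
                                   c("no_split", "split")))
}

new_tree_node <- function(label, weights, depth, split_model = NULL,
                          children = list()) {
  structure(list(label = label, weights = weights, size = sum(weights),
                 depth = depth, split_model = split_model,
                 children = children),
            class = "lct_node")
}

#' Grow a latent class tree
#'
#' Builds the tree by divisive splitting: the root is split into `root_K`
#' classes (gated by the information criterion against the 1-class
#' model), every case is carried into each child with its posterior
#' membership probability as weight, and each new node is then tested
#' recursively with a binary split (breadth-first) until no split is
#' accepted. Children within a split are ordered by size, largest first,
#' and labeled by digit paths: the root's children are "1", "2", ...;
#' deeper nodes append a digit ("21" is the second-largest child of node
#' "2").
#'
#' @param data the root dataset ([lc_data] or [ranking_data]); its weights
#'   (normally 1) are the root node weights
#' @param root_K number of classes at the first split (e.g. chosen with
#'   [select_root_size()]); 1 gives the trivial single-node tree
#' @param criterion `"bic"` (default) or `"aic"` split gate
#' @param adapter model adapter (see [lc_adapter()])
#' @param max_depth maximum node depth (root = 0); default 10
#' @param min_size minimum effective node size to attempt a split,
#'   as a fraction of N if < 1 or an absolute size if >= 1; default 0.01
#' @param k_split_overrides optional named list mapping node labels to a
#'   nonbinary split size for that node
#' @param seed master seed; each node's fits get a deterministic derived
#'   seed, so identical seeds give identical trees and labels
#' @param ic_n BIC sample-size convention (see [em_fit()])
#' @param ... further fit options (`n_starts`, `tol`, ...)
#' @return an object of class `lct_tree` with elements `root` (nested
#'   `lct_node` structure), `n_total`, `criterion`, `settings`
#' @examples
#' \donttest{
#' cfg <- config_profiles("A")
#' d <- simulate_lc(cfg$n_cases, cfg$class_sizes, cfg$profiles, seed = 2)
#' tr <- grow_tree(d, root_K = 2, seed = 2, n_starts = 6)
#' tree_leaves(tr)
#' }
#' @export
grow_tree <- function(data, root_K = 2L, criterion = c("bic", "aic"),
                      adapter = lc_adapter(), max_depth = 10L,
                      min_size = 0.01, k_split_overrides = list(),
                      seed = 1L, ic_n = "total", ...) {
  criterion <- match.arg(criterion)
  root_K <- as.integer(root_K)
  if (root_K < 1L) stop("root_K must be >= 1", call. = FALSE)
  n <- n_cases(data)
  min_abs <- if (min_size < 1) min_size * n else min_size
  # enough deterministic per-node seeds for any tree this size can grow
  node_seeds <- derive_seeds(seed, 2048L)
  seed_idx <- 0L
  next_seed <- function() {
    seed_idx <<- seed_idx + 1L
    node_seeds[seed_idx]
  }

  # flat node table grown breadth-first, assembled into a nested tree after
  nodes <- list(`0` = new_tree_node("0", data$weights, 0L))
  queue <- "0"
  depth_warned <- FALSE
  while (length(queue) > 0L) {
    lab <- queue[1]
    queue <- queue[-1]
    node <- nodes[[lab]]
    node_seed <- next_seed()  # one seed per visited node, in BFS order
    if (node$depth >= max_depth) {
      if (!depth_warned) {
        warning("max_depth = ", max_depth, " reached; growth stopped there")
        depth_warned <- TRUE
      }
      next
    }
    if (node$size < min_abs) next
    k <- if (lab == "0") root_K else 2L
    if (!is.null(k_split_overrides[[lab]])) {
      k <- as.integer(k_split_overrides[[lab]])
    }
    if (k < 2L) next
    res <- try_split(node$weights, data, criterion = criterion, k_split = k,
                     adapter = adapter, seed = node_seed, ic_n = ic_n, ...)
    node$split_decision <- res$criterion
    if (!res$accepted) {
      nodes[[lab]] <- node
      next
    }
    cw <- child_weights(node$weights, res$model$posteriors)
    node$split_model <- res$model
    node$children <- lapply(cw, function(w) {
      new_tree_node("?", w, node$depth + 1L)
    })
    node <- order_children(node)
    node$child_labels <- vapply(node$children, `[[`, character(1), "label")
    for (ch in node$children) nodes[[ch$label]] <- ch
    queue <- c(queue, node$child_labels)
    node$children <- list()  # children linked via labels until assembly
    nodes[[lab]] <- node
  }
  assemble <- function(lab) {
    node <- nodes[[lab]]
    node$children <- lapply(node$child_labels, assemble)
    node$child_labels <- NULL
    node
  }
  root <- assemble("0")
  structure(list(root = root, n_total = n, criterion = criterion,
                 settings = list(root_K = root_K, max_depth = max_depth,
                                 min_size = min_size, seed = seed,
                                 ic_n = ic_n, adapter = adapter$name)),
            class = "lct_tree")
}

#' Order the children of a split node by size
#'
#' Children are sorted largest first and relabeled with consecutive
#' digits appended to the parent label (root children get bare digits).
#' Exact size ties are broken by lexicographic comparison of the
#' class-conditional profile, making labeling deterministic. The split
#' model's classes, proportions and posterior columns are permuted
#' consistently.
#'
#' @param node an `lct_node` whose split has been fitted
#' @return the node with children ordered and relabeled
#' @export
order_children <- function(node) {
  stopifnot(inherits(node, "lct_node"))
  if (length(node$children) == 0L) return(node)
  sizes <- vapply(node$children, `[[`, numeric(1), "size")
  prof_key <- profile_keys(node$split_model$params)
  ord <- order(-sizes, prof_key)
  node$children <- node$children[ord]
  node$split_model <- permute_classes(node$split_model, ord)
  prefix <- if (node$label == "0") "" else node$label
  for (k in seq_along(node$children)) {
    node$children[[k]]$label <- paste0(prefix, k)
  }
  node
}

# one sortable string per class, from its response probabilities/logits
profile_keys <- function(params) {
  if (inherits(params, "ranking_params")) {
    mat <- do.call(cbind, params$beta)
  } else {
    mat <- do.call(cbind, params$response_probs)
  }
  apply(round(mat, 10), 1, paste, collapse = ",")
}

permute_classes <- function(fit, ord) {
  p <- fit$params
  if (inherits(p, "ranking_params")) {
    fit$params <- ranking_params(p$proportions[ord],
                                 lapply(p$beta, function(b) b[ord, , drop = FALSE]))
  } else {
    fit$params <- lc_params(p$proportions[ord],
                            lapply(p$response_probs,
                                   function(m) m[ord, , drop = FALSE]))
  }
  fit$posteriors <- fit$posteriors[, ord, drop = FALSE]
  fit
}

#' Class profile at a split node
#'
#' The parameters of the node-conditional model: child-class proportions
#' and, for the indicator model, the class-conditional response
#' probabilities (for the ranking model, the class-specific logits).
#'
#' @param node an `lct_node` with a fitted split
#' @return list with `proportions`, child `labels`, and `response_probs`
#'   or `beta`
#' @export
node_profile <- function(node) {
  stopifnot(inherits(node, "lct_node"))
  if (is.null(node$split_model)) {
    stop("node '", node$label, "' has not been split", call. = FALSE)
  }
  p <- node$split_model$params
  out <- list(labels = vapply(node$children, `[[`, character(1), "label"),
              proportions = p$proportions)
  if (inherits(p, "ranking_params")) out$beta <- p$beta
  else out$response_probs <- p$response_probs
  out
}

#' Leaves of a latent class tree
#' @param tree an `lct_tree`
#' @return list of leaf `lct_node`s, in label order of discovery
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "lct_tree"))
  out <- list()
  walk <- function(node) {
    if (length(node$children) == 0L) out[[length(out) + 1L]] <<- node
    else for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

#' All nodes of a latent class tree (breadth-first)
#' @param tree an `lct_tree`
#' @return list of `lct_node`s
#' @export
tree_nodes <- function(tree) {
  stopifnot(inherits(tree, "lct_tree"))
  out <- list()
  queue <- list(tree$root)
  while (length(queue) > 0L) {
    node <- queue[[1]]
    queue <- queue[-1]
    out[[length(out) + 1L]] <- node
    queue <- c(queue, node$children)
  }
  out
}

#' @export
print.lct_tree <- function(x, ...) {
  cat("Latent class tree (", x$settings$adapter, " model, ",
      toupper(x$criterion), " splits, n = ", x$n_total, ")\n", sep = "")
  render <- function(node, indent) {
    lab <- if (node$label == "0") "root" else node$label
    cat(indent, lab, " (size ", round(node$size, 1), ")\n", sep = "")
    for (ch in node$children) render(ch, paste0(indent, "  "))
  }
  render(x$root, "")
  invisible(x)
}
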