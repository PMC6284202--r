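# tree growing uses reduced EM settings throughout this file to keep the
# suite quick; the splits involved are well separated and insensitive to
# the number of starts
tree_opts <- list(n_starts = 6, max_iter = 300)

test_that("child weights multiply parent weights by posteriors and conserve mass", {
  set.seed(1)
  w <- runif(20)
  post <- matrix(runif(60), 20, 3)
  post <- post / rowSums(post)
  cw <- child_weights(w, post)
  expect_length(cw, 3)
  expect_equal(Reduce(`+`, cw), w, tolerance = 1e-10)
  expect_equal(cw[[2]], w * post[, 2])

  # single child: weights pass through unchanged
  cw1 <- child_weights(w, matrix(1, 20, 1))
  expect_equal(cw1[[1]], w)

  expect_error(child_weights(w[1:5], post), "number of cases")
})

test_that("a depth-2 weight is the product of its two stage posteriors", {
  cfg <- config_profiles("C")
  d <- simulate_lc(cfg$n_cases, cfg$class_sizes, cfg$profiles, seed = 41)
  tr <- suppressWarnings(do.call(grow_tree,
    c(list(d, root_K = 2, seed = 41), tree_opts)))
  # find a split node at depth 1
  depth1 <- Filter(function(nd) !is.null(nd$split_model),
                   tree_nodes(tr)[-1])
  expect_gte(length(depth1), 1)
  node <- depth1[[1]]
  # independent recomputation: posteriors from the stored stage models,
  # evaluated directly on the full data (posteriors depend only on params)
  p_root <- posterior(d, tr$root$split_model$params)
  root_child_idx <- match(node$label, vapply(tr$root$children, `[[`,
                                             character(1), "label"))
  p_stage1 <- p_root[, root_child_idx]
  p_stage2 <- posterior(d, node$split_model$params)
  for (k in seq_along(node$children)) {
    expect_equal(node$children[[k]]$weights, p_stage1 * p_stage2[, k],
                 tolerance = 1e-8)
  }
})

test_that("split testing accepts structure and rejects noise", {
  # a single repeated response pattern has nothing to split
  d_const <- lc_data(matrix(1L, 50, 4), n_categories = rep(2, 4))
  res <- suppressWarnings(try_split(rep(1, 50), d_const, n_starts = 2))
  expect_false(res$accepted)

  # strong two-class structure is accepted
  d2 <- simulate_lc(1000, c(.5, .5),
                    rbind(rep(.9, 10), rep(.1, 10)), seed = 51)
  r2 <- do.call(try_split, c(list(rep(1, 1000), d2), tree_opts))
  expect_true(r2$accepted)
  expect_lt(r2$criterion["split"], r2$criterion["no_split"])

  # iid coin flips are rejected under BIC
  dn <- simulate_lc(1000, 1, matrix(.5, 1, 10), seed = 52)
  rn <- suppressWarnings(do.call(try_split, c(list(rep(1, 1000), dn), tree_opts)))
  expect_false(rn$accepted)

  # a node far smaller than the parameter count is auto-rejected
  wtiny <- c(rep(1e-3, 10), rep(0, 990))
  warns <- character(0)
  rt <- withCallingHandlers(
    try_split(wtiny, d2, n_starts = 2, max_iter = 100),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_false(rt$accepted)
  expect_true(any(grepl("split rejected", warns)))
})

test_that("pure-noise data yields the trivial single-node tree", {
  dn <- simulate_lc(800, 1, matrix(.5, 1, 8), seed = 61)
  tr <- suppressWarnings(do.call(grow_tree,
    c(list(dn, root_K = 2, seed = 61), tree_opts)))
  expect_length(tr$root$children, 0)
  expect_length(tree_leaves(tr), 1)
})

test_that("configuration A grows a two-split chain of three leaves", {
  cfg <- config_profiles("A")
  d <- simulate_lc(cfg$n_cases, cfg$class_sizes, cfg$profiles, seed = 71)
  tr <- suppressWarnings(do.call(grow_tree,
    c(list(d, root_K = 2, seed = 71), tree_opts)))
  leaves <- tree_leaves(tr)
  expect_length(leaves, 3)
  n_split_children <- sum(vapply(tr$root$children,
                                 function(nd) length(nd$children) > 0,
                                 logical(1)))
  expect_identical(n_split_children, 1L)
})

test_that("configuration C with a binary root grows four leaves in two branches", {
  cfg <- config_profiles("C")
  d <- simulate_lc(cfg$n_cases, cfg$class_sizes, cfg$profiles, seed = 81)
  tr <- suppressWarnings(do.call(grow_tree,
    c(list(d, root_K = 2, seed = 81), tree_opts)))
  leaves <- tree_leaves(tr)
  expect_length(leaves, 4)
  expect_setequal(vapply(leaves, `[[`, character(1), "label"),
                  c("11", "12", "21", "22"))
})

test_that("leaf weights conserve every case across the tree", {
  cfg <- config_profiles("A")
  d <- simulate_lc(cfg$n_cases, cfg$class_sizes, cfg$profiles, seed = 71)
  tr <- suppressWarnings(do.call(grow_tree,
    c(list(d, root_K = 2, seed = 71), tree_opts)))
  leaf_w <- Reduce(`+`, lapply(tree_leaves(tr), `[[`, "weights"))
  expect_equal(leaf_w, rep(1, n_cases(d)), tolerance = 1e-10)
  # node sizes: children sum to parent, leaves sum to n
  for (nd in tree_nodes(tr)) {
    if (length(nd$children) > 0) {
      expect_equal(sum(vapply(nd$children, `[[`, numeric(1), "size")),
                   nd$size, tolerance = 1e-8)
    }
  }
  expect_equal(sum(vapply(tree_leaves(tr), `[[`, numeric(1), "size")),
               tr$n_total, tolerance = 1e-8)
})

test_that("children are ordered by size with deterministic labels", {
  cfg <- config_profiles("A")
  d <- simulate_lc(cfg$n_cases, cfg$class_sizes, cfg$profiles, seed = 71)
  tr1 <- suppressWarnings(do.call(grow_tree,
    c(list(d, root_K = 2, seed = 71), tree_opts)))
  tr2 <- suppressWarnings(do.call(grow_tree,
    c(list(d, root_K = 2, seed = 71), tree_opts)))
  labs1 <- vapply(tree_nodes(tr1), `[[`, character(1), "label")
  labs2 <- vapply(tree_nodes(tr2), `[[`, character(1), "label")
  expect_identical(labs1, labs2)
  for (nd in tree_nodes(tr1)) {
    if (length(nd$children) > 1) {
      sizes <- vapply(nd$children, `[[`, numeric(1), "size")
      expect_true(all(diff(sizes) <= 1e-12))
    }
  }
  # order_children is idempotent
  root2 <- order_children(tr1$root)
  expect_identical(vapply(root2$children, `[[`, character(1), "label"),
                   vapply(tr1$root$children, `[[`, character(1), "label"))
  expect_identical(root2$split_model$params$proportions,
                   tr1$root$split_model$params$proportions)
})

test_that("node profiles recover the generating profiles of configuration A", {
  cfg <- config_profiles("A")
  d <- simulate_lc(2500, cfg$class_sizes, cfg$profiles, seed = 71)
  tr <- suppressWarnings(do.call(grow_tree,
    c(list(d, root_K = 2, seed = 71), tree_opts)))
  # the three leaf classes, each described by its parent's split profile
  leaf_prof <- t(vapply(tree_leaves(tr), function(leaf) {
    parent_label <- substr(leaf$label, 1, nchar(leaf$label) - 1)
    parent <- if (parent_label == "") tr$root else {
      Filter(function(nd) nd$label == parent_label, tree_nodes(tr))[[1]]
    }
    prof <- node_profile(parent)
    k <- match(leaf$label, prof$labels)
    vapply(prof$response_probs, function(m) m[k, 1], numeric(1))
  }, numeric(10)))
  perm <- match_classes(cfg$profiles, leaf_prof)
  expect_lt(max(abs(cfg$profiles - leaf_prof[perm, ])), 0.05)

  expect_error(node_profile(tree_leaves(tr)[[1]]), "not been split")
})

test_that("a rejected binary root gives the trivial tree even for root_K = 2", {
  d_const <- lc_data(matrix(1L, 60, 3), n_categories = rep(2, 3))
  tr <- suppressWarnings(grow_tree(d_const, root_K = 2, n_starts = 2,
                                   seed = 3))
  expect_length(tree_leaves(tr), 1)
})
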