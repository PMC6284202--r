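test_that("weighted log-likelihood matches direct substitution on trivial cases", {
  d1 <- lc_data(matrix(1, 1, 1), weights = 1)
  p1 <- lc_params(1, list(matrix(c(0.5, 0.5), 1)))
  expect_equal(weighted_loglik(d1, p1), log(0.5))

  # zero-weight cases contribute nothing
  d0 <- lc_data(matrix(c(1, 2), 2, 1), weights = c(0, 0))
  expect_identical(weighted_loglik(d0, p1), 0)
})

test_that("weighted log-likelihood equals brute-force class enumeration", {
  for (s in 1:5) {
    set.seed(s)
    d <- lc_data(matrix(sample(1:2, 8, replace = TRUE), 4, 2),
                 weights = runif(4, 0, 2))
    pr <- runif(2, 0.2, 0.8)
    params <- lc_params(c(pr[1], 1 - pr[1]) / 1,
                        list(cbind(pr, 1 - pr),
                             cbind(rev(pr), 1 - rev(pr))))
    expect_equal(weighted_loglik(d, params), brute_force_loglik(d, params),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("loglik and posterior reject dimension mismatch and zero-probability cases", {
  d <- lc_data(matrix(c(1, 2), 2, 1))
  p_wrong <- lc_params(1, list(matrix(c(.5, .5), 1), matrix(c(.5, .5), 1)))
  expect_error(weighted_loglik(d, p_wrong), "items")
  # category 2 has probability 0 in every class -> positive-weight case fails
  p_zero <- lc_params(c(.5, .5), list(rbind(c(1, 0), c(1, 0))))
  expect_error(weighted_loglik(d, p_zero), "zero probability")
})

test_that("posteriors follow Bayes rule and sum to one", {
  d <- lc_data(matrix(c(1, 2, 1), 3, 1))
  # single class: posterior identically 1
  p1 <- lc_params(1, list(matrix(c(.7, .3), 1)))
  expect_equal(posterior(d, p1), matrix(1, 3, 1))

  # identical response profiles: posterior equals the prior everywhere
  pid <- lc_params(c(.3, .7), list(rbind(c(.6, .4), c(.6, .4))))
  expect_equal(posterior(d, pid),
               matrix(c(.3, .7), 3, 2, byrow = TRUE))

  # hand Bayes oracle: pi = (.5, .5), theta_1 = .9, theta_2 = .2, y = 1
  ph <- lc_params(c(.5, .5), list(rbind(c(.9, .1), c(.2, .8))))
  d1 <- lc_data(matrix(1, 1, 1))
  expect_equal(posterior(d1, ph)[1, 1], 0.9 / (0.9 + 0.2))

  # rows always sum to 1
  set.seed(2)
  dd <- lc_data(matrix(sample(1:2, 30, TRUE), 10, 3))
  pp <- lc_params(c(.2, .5, .3),
                  lapply(1:3, function(j) {
                    q <- runif(3, .1, .9)
                    cbind(q, 1 - q)
                  }))
  expect_equal(unname(rowSums(posterior(dd, pp))), rep(1, 10),
               tolerance = 1e-10)
})

test_that("one-class fit is the weighted marginal with its plug-in loglik", {
  d <- toy_data()
  f <- em_fit(d, 1, seed = 1)
  w <- d$weights
  for (j in 1:2) {
    marg <- sapply(1:2, function(cc) sum(w[d$responses[, j] == cc]) / sum(w))
    expect_equal(as.numeric(f$params$response_probs[[j]]), marg,
                 tolerance = 1e-5)
  }
  expect_equal(f$params$proportions, 1)
  expect_equal(f$loglik, weighted_loglik(d, f$params))
})

test_that("EM is monotone within a start and normalizes parameters after every M-step", {
  d <- toy_data()
  post <- matrix(c(.6, .4), nrow(d$responses), 2, byrow = TRUE)
  set.seed(9)
  post <- post + matrix(runif(12, 0, .2), ncol = 2)
  post <- post / rowSums(post)
  ll_prev <- -Inf
  for (it in 1:50) {
    params <- lctree:::m_step(d, post, 1e-6)
    expect_equal(sum(params$proportions), 1, tolerance = 1e-10)
    for (m in params$response_probs) {
      expect_equal(rowSums(m), rep(1, 2), tolerance = 1e-10)
    }
    e <- lctree:::e_step(d, params)
    post <- e$posteriors
    ll <- sum(d$weights * e$case_loglik)
    expect_gte(ll, ll_prev - 1e-8)
    ll_prev <- ll
  }
})

test_that("duplicating a case while halving its weight changes nothing", {
  d <- simulate_lc(300, c(.5, .5), rbind(rep(.85, 4), rep(.15, 4)), seed = 6)
  n <- n_cases(d)
  idx <- c(seq_len(n), 1L)
  w2 <- c(d$weights, 0)
  w2[1] <- d$weights[1] / 2
  w2[n + 1] <- d$weights[1] / 2
  d2 <- lc_data(d$responses[idx, ], weights = w2)
  p <- lc_params(c(.4, .6), lapply(1:4, function(j) {
    rbind(c(.8, .2), c(.3, .7))
  }))
  expect_equal(weighted_loglik(d, p), weighted_loglik(d2, p), tolerance = 1e-12)

  f1 <- em_fit(d, 2, n_starts = 8, seed = 3)
  f2 <- em_fit(d2, 2, n_starts = 8, seed = 3)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(sort(f1$params$proportions), sort(f2$params$proportions),
               tolerance = 1e-3)
})

test_that("permuting class labels leaves the log-likelihood unchanged", {
  d <- toy_data()
  p <- lc_params(c(.3, .7), list(rbind(c(.8, .2), c(.3, .7)),
                                 rbind(c(.6, .4), c(.2, .8))))
  p_perm <- lc_params(p$proportions[2:1],
                      lapply(p$response_probs, function(m) m[2:1, ]))
  expect_equal(weighted_loglik(d, p), weighted_loglik(d, p_perm),
               tolerance = 1e-12)
})

test_that("EM attains the grid-search oracle optimum on small instances", {
  for (s in 1:4) {
    set.seed(100 + s)
    n <- sample(4:8, 1)
    resp <- matrix(sample(1:2, n * 2, replace = TRUE), n, 2)
    w <- rep(1, n)
    d <- lc_data(resp, weights = w, n_categories = c(2, 2))
    f <- suppressWarnings(em_fit(d, 2, n_starts = 16, seed = s,
                                 prob_floor = 1e-9))
    oracle <- grid_oracle_k2(resp, w)
    expect_gte(f$loglik, oracle - 1e-3)
    expect_lte(f$loglik, oracle + 1e-3)
  }
})

test_that("EM recovers a well-separated two-class model at n = 5000", {
  truth <- rbind(rep(.9, 8), rep(.1, 8))
  d <- simulate_lc(5000, c(.5, .5), truth, seed = 17)
  f <- em_fit(d, 2, n_starts = 8, seed = 17)
  fitted <- sapply(f$params$response_probs, function(m) m[, 1])
  perm <- match_classes(truth, fitted)
  expect_lt(max(abs(truth - fitted[perm, ])), 0.03)
  expect_lt(max(abs(sort(f$params$proportions) - .5)), 0.03)
})

test_that("parameter counts and information criteria follow their closed forms", {
  expect_identical(n_parameters(2, rep(2, 18)), 37L)
  expect_identical(n_parameters(1, rep(2, 18)), 18L)
  expect_identical(n_parameters(1, 2), 1L)
  expect_error(n_parameters(0, 2), ">= 1")

  ic <- information_criteria(-94204, 18, 14527)
  expect_equal(round(ic$aic), 188444)
  expect_equal(round(ic$bic), 188581)
  ic0 <- information_criteria(0, 0, 10)
  expect_identical(ic0$bic, 0)
  expect_identical(ic0$aic, 0)
  expect_error(information_criteria(-1, 1, 0), "positive")
})

test_that("overparameterized fits warn about boundary solutions", {
  d <- lc_data(matrix(c(1, 1, 1, 1), 2, 2))  # one distinct pattern
  expect_warning(em_fit(d, 2, n_starts = 2, seed = 1, max_iter = 50),
                 "distinct observed response patterns")
})

test_that("identical seeds give identical fits", {
  d <- simulate_lc(200, c(.5, .5), rbind(rep(.8, 5), rep(.2, 5)), seed = 4)
  f1 <- em_fit(d, 2, n_starts = 4, seed = 11)
  f2 <- em_fit(d, 2, n_starts = 4, seed = 11)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params$proportions, f2$params$proportions)
})
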