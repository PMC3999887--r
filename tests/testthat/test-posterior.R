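test_that("an uninformative source returns the prior", {
  expect_equal(pattern_posterior("1", theta = 0.3, alpha = 0.5, beta = 0.5),
               0.3, tolerance = 1e-12)
  expect_equal(pattern_posterior("0", theta = 0.3, alpha = 0.5, beta = 0.5),
               0.3, tolerance = 1e-12)
})

test_that("posterior matches an independent direct Bayes evaluation", {
  set.seed(7)
  for (i in 1:200) {
    r <- sample(2:6, 1)
    theta <- stats::runif(1, 0.001, 0.5)
    alpha <- stats::runif(r, 0.0005, 0.2)
    beta <- stats::runif(r, 0.01, 0.6)
    x <- stats::rbinom(r, 1, 0.5)
    got <- pattern_posterior(paste(x, collapse = ""), theta, alpha, beta)
    want <- naive_posterior(x, theta, alpha, beta)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("log-space evaluation survives extreme interior parameters", {
  theta <- 1e-6
  alpha <- rep(1e-6, 8)
  beta <- rep(1 - 1e-6, 8)
  x <- rep(1L, 8)
  got <- pattern_posterior(strrep("1", 8), theta, alpha, beta)
  want <- naive_posterior(x, theta, alpha, beta)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(got > 0 && got < 1)
})

test_that("boundary parameters are a hard error", {
  expect_error(pattern_posterior("11", 0.5, c(0, 0.1), c(0.1, 0.1)),
               "strictly inside")
  expect_error(pattern_posterior("11", 1, c(0.1, 0.1), c(0.1, 0.1)),
               "strictly inside")
})

test_that("all-zero pattern has a small but strictly positive posterior", {
  p <- pattern_posterior("000", theta = 0.001, alpha = rep(0.01, 3),
                         beta = rep(0.05, 3))
  expect_gt(p, 0)
  expect_lt(p, 0.001)
})

test_that("posterior table enumerates every pattern exactly once", {
  params <- list(theta = 0.01, alpha = c(0.01, 0.02), beta = c(0.1, 0.2))
  tab <- posterior_table(params)
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$pattern, c("00", "01", "10", "11"))
  expect_equal(tab$posterior,
               pattern_posterior(tab$pattern, params$theta, params$alpha,
                                 params$beta))
  expect_error(posterior_table(list(theta = .1, alpha = rep(.1, 25),
                                    beta = rep(.1, 25))), "24")
})

test_that("identical sources make the posterior depend only on the number
          of agreeing sources", {
  params <- list(theta = 0.02, alpha = rep(0.01, 4), beta = rep(0.2, 4))
  tab <- posterior_table(params)
  by_k <- split(tab$posterior, tab$n_sources)
  for (k in names(by_k)) {
    expect_lt(diff(range(by_k[[k]])), 1e-12)
  }
})

test_that("corroboration never decreases the posterior for
          better-than-chance sources", {
  set.seed(21)
  for (i in 1:20) {
    r <- sample(2:5, 1)
    alpha <- stats::runif(r, 0.001, 0.3)
    beta <- stats::runif(r, 0.05, 1 - alpha - 0.05)  # ensures 1 - beta > alpha
    params <- list(theta = stats::runif(1, 0.001, 0.3),
                   alpha = alpha, beta = beta)
    tab <- posterior_table(params)
    post <- stats::setNames(tab$posterior, tab$pattern)
    X <- pattern_bits(tab$pattern)
    for (p in tab$pattern) {
      x <- X[p, ]
      for (j in which(x == 0)) {
        y <- x
        y[j] <- 1L
        expect_gte(post[bits_to_pattern(y)], post[p])
      }
    }
  }
})

test_that("integration applies the cutoff inclusively over the union", {
  sim <- simulate_call_sets(r = 3, theta = 0.05, alpha = rep(0.05, 3),
                            beta = rep(0.3, 3), total_positions = 5000,
                            seed = 14)
  params <- list(theta = 0.05, alpha = rep(0.05, 3), beta = rep(0.3, 3))
  union_n <- nrow(site_patterns(sim$sites))

  all_in <- integrate_calls(sim$sites, params, cutoff = 0)
  expect_equal(nrow(all_in), union_n)

  none <- integrate_calls(sim$sites, params, cutoff = 1)
  expect_equal(nrow(none), 0)

  tab <- posterior_table(params)
  mid <- integrate_calls(sim$sites, params, cutoff = 0.8)
  keep <- tab$pattern[tab$posterior >= 0.8 - 1e-9]
  expect_setequal(unique(mid$pattern), intersect(keep, unique(
    site_patterns(sim$sites)$pattern)))
  # posterior column equals the table entry for the pattern
  expect_equal(mid$posterior,
               tab$posterior[match(mid$pattern, tab$pattern)])
})

test_that("threshold monotonicity: higher cutoffs give nested subsets", {
  fx <- acceptance_fixture()
  cutoffs <- c(0, 0.25, 0.5, 0.8, 0.9, 0.99, 1)
  prev <- NULL
  for (cc in cutoffs) {
    cur <- integrate_calls(fx$sim$sites, fx$fit, cutoff = cc)
    keys <- paste(cur$chrom, cur$pos, cur$ref, cur$alt)
    if (!is.null(prev)) {
      expect_true(all(keys %in% prev))
    }
    prev <- keys
  }
})

test_that("precision against truth is non-decreasing in the cutoff", {
  fx <- acceptance_fixture()
  truth_keys <- paste(fx$sim$truth$chrom, fx$sim$truth$pos,
                      fx$sim$truth$ref, fx$sim$truth$alt)
  prec <- vapply(c(0.8, 0.9), function(cc) {
    calls <- integrate_calls(fx$sim$sites, fx$fit, cutoff = cc)
    keys <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
    mean(keys %in% truth_keys)
  }, numeric(1))
  # monotone in expectation; allow binomial sampling noise on ~2000 calls
  expect_gte(prec[2], prec[1] - 0.005)
})

test_that("pattern posteriors are calibrated at the generating parameters", {
  fx <- acceptance_fixture()
  spec <- fx$sim$spec
  tab <- posterior_table(list(theta = spec$theta, alpha = spec$alpha,
                              beta = spec$beta))
  sp <- site_patterns(fx$sim$sites)
  truth_keys <- paste(fx$sim$truth$chrom, fx$sim$truth$pos,
                      fx$sim$truth$ref, fx$sim$truth$alt)
  sp$is_true <- paste(sp$chrom, sp$pos, sp$ref, sp$alt) %in% truth_keys
  per_pattern <- dplyr::summarise(dplyr::group_by(sp, pattern),
                                  n = dplyr::n(), frac = mean(is_true))
  per_pattern <- dplyr::inner_join(per_pattern, tab, by = "pattern")
  big <- per_pattern[per_pattern$n >= 50, ]
  expect_gt(nrow(big), 3)
  # empirical true fraction within 4 binomial sigmas of the posterior
  sigma <- sqrt(big$posterior * (1 - big$posterior) / big$n)
  expect_true(all(abs(big$frac - big$posterior) <= 4 * sigma + 1e-9))
})
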