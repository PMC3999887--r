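#' Fit the two-class latent class model by Gibbs sampling
#'
#' Each assayable position belongs to an unobserved class -- true variant
#' (with prior probability `theta`) or not -- and each evidence source calls
#' it independently given the class: a true variant is missed with
#' probability `beta[i]` (false-negative rate of source *i*), a non-variant
#' position is called with probability `alpha[i]` (false-positive rate). The
#' observed data are the pattern counts `n_k` over the `2^r` agreement
#' patterns, including the derived all-zero cell.
#'
#' All parameters carry conjugate Beta(`prior[1]`, `prior[2]`) priors
#' (default Beta(1, 2), mildly favouring small rates). The sampler alternates
#' (1) splitting each pattern count `n_k` into latent true/false counts by a
#' binomial draw at the current per-pattern membership probability,
#' (2) drawing `theta` from its Beta full conditional, and (3) drawing each
#' `alpha[i]`, `beta[i]` from theirs. All full conditionals are exact, so
#' every draw is accepted.
#'
#' The two-class model is invariant under swapping the class labels. Draws
#' for which the "true" class is the worse-detected one (mean over sources of
#' `1 - beta[i]` below mean of `alpha[i]`) are relabelled
#' (`theta -> 1 - theta`, `alpha <-> 1 - beta`); the relabel count is
#' reported as a diagnostic -- on identifiable data it should be zero or
#' nearly so.
#'
#' @param counts An `lca_pattern_counts` table from [pattern_counts()] (or
#'   any tibble with columns `pattern`, `n` covering all `2^r` patterns and a
#'   `total_positions` attribute or argument).
#' @param iterations Total MCMC iterations (default 120000).
#' @param burn_in Iterations discarded before retaining draws (default 20000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 10).
#' @param prior Length-2 Beta shape parameters (a, b) shared by `theta`,
#'   `alpha`, `beta`. Default `c(1, 2)`.
#' @param chains Number of independent chains; per-chain seeds are derived
#'   deterministically from `seed`. Retained draws are pooled.
#' @param seed Integer seed making the run reproducible; `NULL` leaves the
#'   RNG state alone.
#' @return An object of class `lca_fit`: a list with elements
#'   * `theta`, `alpha`, `beta` -- posterior-mean point estimates,
#'   * `summary` -- tibble of per-parameter mean, sd, 2.5/97.5 percentiles
#'     and effective sample size,
#'   * `draws` -- matrix of retained draws (pooled over chains),
#'   * `relabel_count` -- label-switch corrections applied,
#'   * `sources`, `r`, `total_positions`, `config`.
#' @seealso [fit_lca_em()] for the maximum-likelihood fit of the same model;
#'   [posterior_table()] and [integrate_calls()] to apply the fit.
#' @export
fit_lca_gibbs <- function(counts, iterations = 120000, burn_in = 20000,
                          thin = 10, prior = c(1, 2), chains = 1,
                          seed = NULL) {
  ct <- check_counts(counts)
  stopifnot(iterations > burn_in, burn_in >= 0, thin >= 1,
            length(prior) == 2, all(prior > 0), chains >= 1)
  if (ct$r < 2) {
    stop("model not identifiable with one source; provide at least two ",
         "call sets", call. = FALSE)
  }

  chain_seeds <- if (is.null(seed)) rep(list(NULL), chains) else {
    as.list(seed + 1000L * (seq_len(chains) - 1L))
  }
  runs <- lapply(chain_seeds, function(s) {
    run_gibbs_chain(ct, iterations, burn_in, thin, prior, s)
  })
  draws <- do.call(rbind, lapply(runs, `[[`, "draws"))
  relabel_count <- sum(vapply(runs, `[[`, numeric(1), "relabels"))

  est <- colMeans(draws)
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  summary <- tibble::tibble(
    parameter = colnames(draws),
    mean = unname(est),
    sd = apply(draws, 2, stats::sd),
    lower = qs[1, ],
    upper = qs[2, ],
    ess = apply(draws, 2, ess_estimate)
  )

  structure(
    list(
      theta = unname(est["theta"]),
      alpha = unname(est[grep("^alpha", colnames(draws))]),
      beta = unname(est[grep("^beta", colnames(draws))]),
      summary = summary,
      draws = draws,
      relabel_count = relabel_count,
      sources = ct$sources,
      r = ct$r,
      total_positions = ct$total,
      config = list(iterations = iterations, burn_in = burn_in, thin = thin,
                    prior = prior, chains = chains, seed = seed),
      method = "gibbs"
    ),
    class = "lca_fit"
  )
}

run_gibbs_chain <- function(ct, iterations, burn_in, thin, prior, seed) {
  if (!is.null(seed)) set.seed(seed)
  r <- ct$r
  K <- nrow(ct$X)
  X <- ct$X
  Xc <- 1 - X
  n <- ct$n
  Tt <- ct$total
  a <- prior[1]
  b <- prior[2]

  init <- moment_init(ct)
  theta <- init$theta
  alpha <- init$alpha
  beta <- init$beta

  n_keep <- floor((iterations - burn_in) / thin)
  draws <- matrix(NA_real_, n_keep, 1 + 2 * r)
  colnames(draws) <- c("theta", paste0("alpha", seq_len(r)),
                       paste0("beta", seq_len(r)))
  kept <- 0L
  relabels <- 0L

  for (it in seq_len(iterations)) {
    # membership probability of each pattern under current parameters
    p <- class_membership(X, Xc, theta, alpha, beta)
    t_k <- stats::rbinom(K, n, p)
    f_k <- n - t_k

    St <- sum(t_k)
    theta <- stats::rbeta(1, a + St, b + Tt - St)
    # beta_i: true sites missed (x_i = 0) vs detected (x_i = 1)
    beta <- stats::rbeta(r, a + colSums(t_k * Xc), b + colSums(t_k * X))
    # alpha_i: false sites called (x_i = 1) vs not called (x_i = 0)
    alpha <- stats::rbeta(r, a + colSums(f_k * X), b + colSums(f_k * Xc))

    # identifiability: the true class must be the better-detected one
    if (mean(1 - beta) < mean(alpha)) {
      relabels <- relabels + 1L
      theta <- 1 - theta
      old_alpha <- alpha
      alpha <- 1 - beta
      beta <- 1 - old_alpha
    }

    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- c(theta, alpha, beta)
    }
  }
  list(draws = draws[seq_len(kept), , drop = FALSE], relabels = relabels)
}

# Per-pattern probability of the true class, computed in log space.
class_membership <- function(X, Xc, theta, alpha, beta) {
  lt <- log(theta) + drop(X %*% log1p(-beta) + Xc %*% log(beta))
  lf <- log1p(-theta) + drop(X %*% log(alpha) + Xc %*% log1p(-alpha))
  1 / (1 + exp(lf - lt))
}

# Moment-style start: theta from the union fraction, alpha from sites unique
# to each source, beta from each source's coverage of the union. Cheap, and
# lands on the intended (better-detected true class) side of the mode.
moment_init <- function(ct, clip = 1e-6) {
  X <- ct$X
  n <- ct$n
  Tt <- ct$total
  union <- sum(n[rowSums(X) > 0])
  in_src <- colSums(n * X)
  uniq <- colSums(n * (X * (rowSums(X) == 1)))
  theta <- union / Tt
  alpha <- uniq / Tt
  beta <- if (union > 0) 1 - in_src / union else rep(0.5, ct$r)
  clipv <- function(x) pmin(pmax(x, clip), 1 - clip)
  list(theta = clipv(theta), alpha = clipv(alpha), beta = clipv(beta))
}

# Effective sample size from the initial positive sequence of autocorrelations.
ess_estimate <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(NA_real_)
  lag_max <- min(n - 1, 200L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  cut <- which(rho < 0.05)[1]
  if (!is.na(cut)) rho <- rho[seq_len(cut - 1)]
  n / (1 + 2 * sum(rho))
}

#' Fit the two-class latent class model by EM (maximum likelihood)
#'
#' Maximum-likelihood counterpart of [fit_lca_gibbs()] for the same
#' multinomial likelihood over pattern counts. The E-step assigns each
#' pattern its class-membership probability under the current parameters;
#' the M-step sets `theta`, `alpha`, `beta` to the complete-data frequencies.
#' The observed-data log-likelihood is non-decreasing across iterations.
#' Useful as a fast fit and as an independent check on the sampler.
#'
#' @inheritParams fit_lca_gibbs
#' @param tol Convergence threshold on the maximum absolute parameter change.
#' @param max_iter Iteration cap; non-convergence yields a warning and the
#'   best-so-far estimate flagged `converged = FALSE`.
#' @param init Optional list with `theta`, `alpha`, `beta` start values;
#'   defaults to the same moment-style start as the sampler.
#' @return An object of class `lca_em`: list with `theta`, `alpha`, `beta`,
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `sources`, `r`,
#'   `total_positions`.
#' @export
fit_lca_em <- function(counts, tol = 1e-8, max_iter = 5000, init = NULL) {
  ct <- check_counts(counts)
  if (ct$r < 2) {
    stop("model not identifiable with one source; provide at least two ",
         "call sets", call. = FALSE)
  }
  X <- ct$X
  Xc <- 1 - X
  n <- ct$n
  Tt <- ct$total
  eps <- 1e-12

  if (is.null(init)) init <- moment_init(ct)
  theta <- init$theta
  alpha <- init$alpha
  beta <- init$beta

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- class_membership(X, Xc, theta, alpha, beta)
    nt <- n * p
    nf <- n - nt

    theta_new <- sum(nt) / Tt
    st <- sum(nt)
    sf <- sum(nf)
    beta_new <- if (st > 0) colSums(nt * Xc) / st else beta
    alpha_new <- if (sf > 0) colSums(nf * X) / sf else alpha

    clipv <- function(x) pmin(pmax(x, eps), 1 - eps)
    theta_new <- clipv(theta_new)
    alpha_new <- clipv(alpha_new)
    beta_new <- clipv(beta_new)

    delta <- max(abs(c(theta_new - theta, alpha_new - alpha,
                       beta_new - beta)))
    theta <- theta_new
    alpha <- alpha_new
    beta <- beta_new
    trace <- c(trace, lca_loglik(counts, theta, alpha, beta))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter, " iterations; returning ",
            "best-so-far estimates", call. = FALSE)
  }
  # resolve the label-switching mode as the sampler does
  if (mean(1 - beta) < mean(alpha)) {
    theta <- 1 - theta
    old_alpha <- alpha
    alpha <- 1 - beta
    beta <- 1 - old_alpha
  }
  structure(
    list(theta = theta, alpha = alpha, beta = beta,
         loglik = trace[length(trace)], loglik_trace = trace,
         n_iter = length(trace), converged = converged,
         sources = ct$sources, r = ct$r, total_positions = ct$total,
         method = "em"),
    class = "lca_em"
  )
}

#' Observed-data log-likelihood of the latent class model
#'
#' The multinomial mixture log-likelihood
#' `sum_k n_k * log(theta * P(x_k | true) + (1 - theta) * P(x_k | false))`
#' where `P(x | true) = prod_i beta_i^(1-x_i) (1-beta_i)^x_i` and
#' `P(x | false) = prod_i alpha_i^x_i (1-alpha_i)^(1-x_i)`. Evaluated in log
#' space (log-sum-exp per pattern), so it is finite for any parameters
#' strictly inside (0, 1).
#'
#' @inheritParams fit_lca_gibbs
#' @param theta,alpha,beta Model parameters, strictly inside (0, 1);
#'   `alpha`, `beta` of length `r`.
#' @return A single finite number.
#' @export
lca_loglik <- function(counts, theta, alpha, beta) {
  ct <- check_counts(counts)
  stopifnot(length(alpha) == ct$r, length(beta) == ct$r)
  check_interior(theta, alpha, beta)
  X <- ct$X
  Xc <- 1 - X
  lt <- log(theta) + drop(X %*% log1p(-beta) + Xc %*% log(beta))
  lf <- log1p(-theta) + drop(X %*% log(alpha) + Xc %*% log1p(-alpha))
  m <- pmax(lt, lf)
  sum(ct$n * (m + log(exp(lt - m) + exp(lf - m))))
}

check_interior <- function(theta, alpha, beta) {
  v <- c(theta, alpha, beta)
  if (any(v <= 0 | v >= 1)) {
    stop("parameters must lie strictly inside (0, 1); clip boundary values ",
         "before use", call. = FALSE)
  }
  invisible(NULL)
}

# Normalize a pattern-count table into the pieces the fitters need.
check_counts <- function(counts, total_positions = NULL) {
  stopifnot(is.data.frame(counts), all(c("pattern", "n") %in% names(counts)))
  r <- attr(counts, "r") %||% nchar(counts$pattern[1])
  if (nrow(counts) != 2^r || anyDuplicated(counts$pattern)) {
    stop("counts must contain each of the 2^r patterns exactly once",
         call. = FALSE)
  }
  if (any(counts$n < 0)) stop("pattern counts must be >= 0", call. = FALSE)
  total <- total_positions %||% attr(counts, "total_positions") %||%
    sum(counts$n)
  if (abs(total - sum(counts$n)) > 0.5) {
    stop("pattern counts do not sum to total_positions", call. = FALSE)
  }
  # canonical binary order so bit matrices line up across calls
  ord <- order(counts$pattern)
  counts <- counts[ord, ]
  X <- pattern_bits(counts$pattern)
  list(X = X, n = as.numeric(counts$n), total = total, r = r,
       sources = attr(counts, "sources") %||% paste0("source", seq_len(r)),
       pattern = counts$pattern)
}

lca_point <- function(fit) {
  stopifnot(inherits(fit, "lca_fit") || inherits(fit, "lca_em"))
  list(theta = fit$theta, alpha = fit$alpha, beta = fit$beta)
}

#' @export
print.lca_fit <- function(x, ...) {
  cat("Latent class fit (Gibbs), ", x$r, " sources, T = ",
      format(x$total_positions, scientific = FALSE, big.mark = ","), "\n",
      sep = "")
  cat("  retained draws: ", nrow(x$draws),
      "  relabel corrections: ", x$relabel_count, "\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' @export
print.lca_em <- function(x, ...) {
  cat("Latent class fit (EM), ", x$r, " sources, T = ",
      format(x$total_positions, scientific = FALSE, big.mark = ","),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("  log-likelihood: ", format(x$loglik), " after ", x$n_iter,
      " iterations\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy and summarise latent class fits
#'
#' `tidy()` returns one row per model parameter; for Gibbs fits the posterior
#' mean, sd and central 95% interval, for EM fits the point estimate.
#' `glance()` returns a one-row model summary.
#'
#' @param x An `lca_fit` or `lca_em` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lca_fit
#' @export
tidy.lca_fit <- function(x, ...) {
  s <- x$summary
  s$source <- param_source(s$parameter, x$sources)
  dplyr::relocate(s, "parameter", "source")
}

#' @rdname tidy.lca_fit
#' @method tidy lca_em
#' @export
tidy.lca_em <- function(x, ...) {
  param <- c("theta", paste0("alpha", seq_len(x$r)),
             paste0("beta", seq_len(x$r)))
  tibble::tibble(
    parameter = param,
    source = param_source(param, x$sources),
    estimate = c(x$theta, x$alpha, x$beta)
  )
}

#' @rdname tidy.lca_fit
#' @method glance lca_fit
#' @export
glance.lca_fit <- function(x, ...) {
  tibble::tibble(
    r = x$r,
    total_positions = x$total_positions,
    theta = x$theta,
    n_draws = nrow(x$draws),
    relabel_count = x$relabel_count,
    min_ess = min(x$summary$ess, na.rm = TRUE),
    iterations = x$config$iterations,
    burn_in = x$config$burn_in,
    thin = x$config$thin,
    chains = x$config$chains
  )
}

#' @rdname tidy.lca_fit
#' @method glance lca_em
#' @export
glance.lca_em <- function(x, ...) {
  tibble::tibble(
    r = x$r,
    total_positions = x$total_positions,
    theta = x$theta,
    loglik = x$loglik,
    n_iter = x$n_iter,
    converged = x$converged
  )
}

param_source <- function(parameter, sources) {
  idx <- suppressWarnings(as.integer(sub("^(alpha|beta)", "", parameter)))
  out <- ifelse(is.na(idx), NA_character_, sources[idx])
  out
}
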