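#' Posterior probability that a site with a given agreement pattern is a
#' true variant
#'
#' Closed-form Bayes' rule on the two-class model: for pattern
#' `x = (x_1, ..., x_r)`,
#' \deqn{P(\mathrm{true} \mid x) =
#'   \frac{\theta \prod_i \beta_i^{1-x_i} (1-\beta_i)^{x_i}}
#'        {\theta \prod_i \beta_i^{1-x_i} (1-\beta_i)^{x_i} +
#'         (1-\theta) \prod_i \alpha_i^{x_i} (1-\alpha_i)^{1-x_i}}.}
#' Both products are evaluated in log space and combined with a numerically
#' stable logistic, so large `r` and extreme rates do not underflow.
#'
#' @param pattern Character vector of bit-string patterns (`"0101"`, leftmost
#'   bit = first source), or a 0/1 matrix with one row per pattern.
#' @inheritParams lca_loglik
#' @return Numeric vector of posterior probabilities in (0, 1), one per
#'   pattern.
#' @export
#' @examples
#' pattern_posterior("11", theta = 0.01,
#'                   alpha = c(0.001, 0.002), beta = c(0.10, 0.20))
pattern_posterior <- function(pattern, theta, alpha, beta) {
  check_interior(theta, alpha, beta)
  X <- if (is.matrix(pattern)) pattern else pattern_bits(pattern)
  stopifnot(ncol(X) == length(alpha), length(alpha) == length(beta))
  Xc <- 1 - X
  lt <- log(theta) + drop(X %*% log1p(-beta) + Xc %*% log(beta))
  lf <- log1p(-theta) + drop(X %*% log(alpha) + Xc %*% log1p(-alpha))
  unname(stats::plogis(lt - lf))
}

#' Posterior probabilities for every possible agreement pattern
#'
#' Enumerates all `2^r` patterns and evaluates [pattern_posterior()] once per
#' pattern; downstream per-site lookup is an exact table join, so sites
#' sharing a pattern always share a posterior (a property of the model: no
#' per-site covariate enters).
#'
#' @param fit An `lca_fit` / `lca_em` object, or a list with elements
#'   `theta`, `alpha`, `beta`.
#' @param r Number of sources; inferred from the fit when omitted. Must be
#'   24 or fewer.
#' @return A tibble with columns `pattern`, `n_sources` (set bits) and
#'   `posterior`, covering all `2^r` patterns.
#' @export
posterior_table <- function(fit, r = NULL) {
  pt <- if (inherits(fit, "lca_fit") || inherits(fit, "lca_em")) {
    lca_point(fit)
  } else {
    stopifnot(is.list(fit), all(c("theta", "alpha", "beta") %in% names(fit)))
    fit
  }
  r <- r %||% length(pt$alpha)
  stopifnot(length(pt$alpha) == r, length(pt$beta) == r)
  pats <- all_patterns(r)
  tibble::tibble(
    pattern = pats,
    n_sources = stringr::str_count(pats, stringr::fixed("1")),
    posterior = pattern_posterior(pats, pt$theta, pt$alpha, pt$beta)
  )
}

#' Integrate the union call set by posterior filtering
#'
#' Assigns every union site its agreement pattern and pattern posterior, and
#' keeps the sites whose posterior is at least `cutoff`. The comparison is
#' inclusive (`>=`) so that a cutoff of 1.0 still retains posteriors that
#' round to 1 within 1e-9 -- with parameters strictly inside (0, 1) no
#' pattern attains exactly 1, and an exclusive comparison would make the
#' maximal-specificity setting always empty.
#'
#' @inheritParams site_patterns
#' @param fit An `lca_fit` / `lca_em` object or `list(theta, alpha, beta)`.
#' @param cutoff Posterior probability cutoff in \[0, 1\] (default 0.8;
#'   0.9 trades a little sensitivity for higher specificity).
#' @param keep_all Return all union sites with a logical `pass` column
#'   instead of only the surviving ones?
#' @return A tibble of integrated calls, sorted by (chrom, pos, alt):
#'   `chrom`, `pos`, `ref`, `alt`, `pattern`, `n_sources`, `sources`,
#'   `posterior` (and `pass` when `keep_all = TRUE`).
#' @export
integrate_calls <- function(sites, fit, cutoff = 0.8, sources = NULL,
                            match_by = c("allele", "position"),
                            keep_all = FALSE) {
  stopifnot(length(cutoff) == 1, cutoff >= 0, cutoff <= 1)
  match_by <- match.arg(match_by)
  fit_sources <- if (inherits(fit, "lca_fit") || inherits(fit, "lca_em")) {
    fit$sources
  } else {
    NULL
  }
  sources <- sources %||% attr(sites, "source_names") %||% fit_sources
  sp <- site_patterns(sites, sources = sources, match_by = match_by)
  tab <- posterior_table(fit, r = length(attr(sp, "sources")))
  out <- dplyr::left_join(sp, tab[, c("pattern", "posterior")],
                          by = "pattern")
  out$pass <- out$posterior >= cutoff - 1e-9
  out <- sort_sites(out, attr(sp, "contigs"))
  if (!keep_all) {
    out <- out[out$pass, , drop = FALSE]
    out$pass <- NULL
  }
  attr(out, "contigs") <- attr(sp, "contigs")
  attr(out, "cutoff") <- cutoff
  out
}
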