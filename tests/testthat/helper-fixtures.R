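# Shared fixtures and independent oracles for the test suite.

# Write a minimal VCF to a temp file and return its path.
local_vcf <- function(records, meta = character(),
                      env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = env)
  writeLines(c(
    "##fileformat=VCFv4.2",
    meta,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    records
  ), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, qual = ".", filter = "PASS") {
  sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t.", chrom, pos, ref, alt, qual, filter)
}

# Build a stacked site tibble by hand: x is a named list source -> list of
# "chrom:pos:ref:alt" strings.
make_sites <- function(x) {
  if (length(x) == 0) {
    return(tibble::tibble(source = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character()))
  }
  purrr::imap_dfr(x, function(keys, nm) {
    if (length(keys) == 0) {
      return(tibble::tibble(source = character(), chrom = character(),
                            pos = integer(), ref = character(),
                            alt = character()))
    }
    parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
    tibble::tibble(source = nm, chrom = parts[, 1],
                   pos = as.integer(parts[, 2]),
                   ref = parts[, 3], alt = parts[, 4])
  })
}

# Independent per-site brute-force pattern tally: loops over every union
# site and every source, no grouping machinery shared with the package.
naive_pattern_tally <- function(sites, sources, total_positions,
                                match_by = "allele") {
  key_of <- function(df) {
    if (match_by == "allele") {
      paste(df$chrom, df$pos, df$ref, df$alt)
    } else {
      paste(df$chrom, df$pos)
    }
  }
  per_source <- lapply(sources, function(s) {
    unique(key_of(sites[sites$source == s, , drop = FALSE]))
  })
  union_keys <- unique(unlist(per_source))
  counts <- stats::setNames(rep(0, 2^length(sources)),
                            all_patterns(length(sources)))
  for (k in union_keys) {
    bits <- vapply(per_source, function(sk) k %in% sk, logical(1))
    pat <- paste(as.integer(bits), collapse = "")
    counts[pat] <- counts[pat] + 1
  }
  counts[strrep("0", length(sources))] <- total_positions - length(union_keys)
  counts
}

# Independent direct-arithmetic Bayes evaluation of the per-pattern
# posterior (no logs, no code shared with pattern_posterior()).
naive_posterior <- function(x, theta, alpha, beta) {
  num <- theta * prod(beta^(1 - x) * (1 - beta)^x)
  den <- num + (1 - theta) * prod(alpha^x * (1 - alpha)^(1 - x))
  num / den
}

# Random small site fixture over a handful of positions; membership chosen
# uniformly so every pattern can occur.
random_fixture <- function(n_sources, n_sites, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  keys <- sprintf("chr%d:%d:%s:%s",
                  sample(1:2, n_sites, TRUE),
                  sample(1:1000, n_sites),
                  "A", sample(c("C", "G", "T"), n_sites, TRUE))
  keys <- unique(keys)
  src <- paste0("s", seq_len(n_sources))
  membership <- lapply(src, function(s) {
    keys[stats::runif(length(keys)) < 0.5]
  })
  names(membership) <- src
  make_sites(membership)
}

# The parameter-recovery workhorse: simulated once per session and cached,
# together with its full-length Gibbs and EM fits.
acceptance_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_call_sets(
        r = 4, theta = 0.01,
        alpha = c(0.002, 0.005, 0.001, 0.01),
        beta = c(0.1, 0.2, 0.15, 0.3),
        total_positions = 2e5, seed = 20140412
      )
      counts <- pattern_counts(sim$sites, total_positions = 2e5)
      fit <- fit_lca_gibbs(counts, iterations = 120000, burn_in = 20000,
                           thin = 10, seed = 101)
      em <- fit_lca_em(counts)
      cache <<- list(sim = sim, counts = counts, fit = fit, em = em)
    }
    cache
  }
})
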