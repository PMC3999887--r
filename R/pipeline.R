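#' Run the full call-set integration pipeline
#'
#' Reads the input VCFs, tabulates agreement patterns over the union of
#' sites, fits the latent class model by Gibbs sampling, computes the
#' per-pattern posteriors, filters at the cutoff and writes three artifacts:
#' the integrated VCF, a pattern/posterior report (tab-separated: pattern bit
#' string, asserting sources, count, posterior) and a parameter report (both
#' tab-separated and JSON, echoing the configuration, seed, total positions,
#' all-zero count and relabel diagnostics). Identical configuration and seed
#' produce byte-identical reports.
#'
#' Database sources (dbSNP/COSMIC-style VCFs) are ordinary evidence sources
#' to the model; the `db` argument only labels them in reports.
#'
#' @param vcf Named character vector of caller VCF paths (names = source
#'   labels; unnamed entries are labelled from the file name). Order fixes
#'   pattern bit order.
#' @param db Optional named character vector of database VCF paths, appended
#'   after the callers.
#' @param total_positions Assayable-region size T (see [pattern_counts()]).
#'   Default 3e9, human whole-genome scale; set to the callable-target size
#'   (e.g. exome footprint) whenever one is known.
#' @param out_vcf,out_params,out_patterns Output paths; `NULL` skips that
#'   artifact.
#' @inheritParams integrate_calls
#' @inheritParams read_vcf_sites
#' @inheritParams fit_lca_gibbs
#' @return Invisibly, a list with `sites`, `counts`, `fit`, `posteriors`
#'   (the full pattern table), `calls` (the integrated set) and the output
#'   paths.
#' @export
run_integration <- function(vcf, db = NULL, cutoff = 0.8,
                            total_positions = 3e9,
                            match_by = c("allele", "position"),
                            pass_only = FALSE,
                            iterations = 120000, burn_in = 20000, thin = 10,
                            chains = 1, seed = NULL,
                            out_vcf = NULL, out_params = NULL,
                            out_patterns = NULL) {
  match_by <- match.arg(match_by)
  paths <- c(vcf, db)
  if (length(paths) < 1) stop("no input VCFs given", call. = FALSE)
  kinds <- c(rep("caller", length(vcf)), rep("database", length(db)))

  sites <- read_vcf_sources(paths, pass_only = pass_only)
  sources <- attr(sites, "source_names")
  counts <- pattern_counts(sites, total_positions = total_positions,
                           sources = sources, match_by = match_by)
  fit <- fit_lca_gibbs(counts, iterations = iterations, burn_in = burn_in,
                       thin = thin, chains = chains, seed = seed)
  posteriors <- posterior_table(fit)
  calls <- integrate_calls(sites, fit, cutoff = cutoff, sources = sources,
                           match_by = match_by)

  if (!is.null(out_vcf)) {
    write_integrated_vcf(calls, out_vcf, fit = fit, cutoff = cutoff,
                         total_positions = total_positions,
                         contig_order = attr(sites, "contigs"))
  }
  if (!is.null(out_patterns)) {
    write_pattern_report(counts, posteriors, out_patterns)
  }
  if (!is.null(out_params)) {
    write_parameter_report(fit, out_params,
                           kinds = stats::setNames(kinds, sources),
                           cutoff = cutoff, match_by = match_by)
  }
  invisible(list(sites = sites, counts = counts, fit = fit,
                 posteriors = posteriors, calls = calls,
                 out_vcf = out_vcf, out_params = out_params,
                 out_patterns = out_patterns))
}

#' Write the pattern/posterior report
#'
#' One row per agreement pattern: bit string, the source names it asserts,
#' the observed count, and the fitted posterior probability -- the
#' contingency-table view of the run. Tab-separated; deterministic for a
#' given fit.
#'
#' @param counts An `lca_pattern_counts` table.
#' @param posteriors A posterior table from [posterior_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pattern_report <- function(counts, posteriors, path) {
  sources <- attr(counts, "sources")
  tab <- dplyr::inner_join(as.data.frame(counts), posteriors, by = "pattern")
  tab$sources <- vapply(tab$pattern, function(p) {
    on <- pattern_bits(p)[1, ] == 1
    if (!any(on)) "(none)" else paste(sources[on], collapse = ",")
  }, character(1))
  tab <- tab[order(tab$pattern), c("pattern", "sources", "n", "posterior")]
  tab$posterior <- sprintf("%.6f", tab$posterior)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Write the parameter report
#'
#' The fitted parameter summary (mean, sd, central 95% interval, effective
#' sample size per parameter), the run configuration, and diagnostics, as a
#' tab-separated table plus a JSON sidecar (`<path>.json`). Contains no
#' timestamps, so identical runs produce identical bytes.
#'
#' @param fit An `lca_fit` object.
#' @param path Output path for the TSV; the JSON goes to `paste0(path,
#'   ".json")`.
#' @param kinds Optional named character vector labelling each source as
#'   `caller` or `database`.
#' @param cutoff,match_by Configuration echoes.
#' @return `path`, invisibly.
#' @export
write_parameter_report <- function(fit, path, kinds = NULL, cutoff = NULL,
                                   match_by = NULL) {
  s <- tidy(fit)
  s$kind <- if (is.null(kinds)) NA_character_ else unname(kinds[s$source])
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], function(x) sprintf("%.8g", x))
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(
    sprintf("# sources\t%s", paste(fit$sources, collapse = ",")),
    sprintf("# total_positions\t%s",
            format(fit$total_positions, scientific = FALSE)),
    sprintf("# iterations\t%d", fit$config$iterations),
    sprintf("# burn_in\t%d", fit$config$burn_in),
    sprintf("# thin\t%d", fit$config$thin),
    sprintf("# chains\t%d", fit$config$chains),
    sprintf("# seed\t%s", fit$config$seed %||% "NULL"),
    sprintf("# relabel_count\t%d", fit$relabel_count),
    if (!is.null(cutoff)) sprintf("# cutoff\t%s", format(cutoff)),
    if (!is.null(match_by)) sprintf("# match_by\t%s", match_by)
  )
  writeLines(meta, con)
  writeLines(paste(names(s), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(s)), sep = "\t")), con)

  js <- list(
    sources = fit$sources,
    kinds = kinds,
    total_positions = fit$total_positions,
    config = fit$config,
    cutoff = cutoff,
    match_by = match_by,
    relabel_count = fit$relabel_count,
    estimates = tidy(fit)
  )
  jsonlite::write_json(js, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
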