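#' Simulate multi-caller SNP call sets with known truth
#'
#' Draws data from exactly the generative process the latent class model
#' assumes: each of `total_positions` positions on one artificial contig is
#' independently a true variant with probability `theta`; source *i* then
#' calls a true position with probability `1 - beta[i]` and a false position
#' with probability `alpha[i]`, independently across sources given the truth
#' (the model's iid assumption). Because real callers share error modes
#' (alignment artefacts, low-coverage regions), real data violate that
#' independence; simulations here validate the machinery, not the iid
#' assumption itself.
#'
#' Each position is given a reference and one alternate allele so that the
#' transition/transversion ratio is `titv_true` among true variants and
#' `titv_false` among false-positive positions in expectation (defaults 2.0
#' and 0.5: the values typical of real human SNPs and of random artefacts).
#' All sources calling a position report the same allele, so allele and
#' position matching agree on simulated data.
#'
#' @param r Number of evidence sources.
#' @param theta Probability a position is a true variant.
#' @param alpha,beta Length-`r` false-positive and false-negative rates,
#'   strictly in (0, 1).
#' @param total_positions Number of assayable positions T (positions are
#'   1..T on `contig`).
#' @param seed Integer seed; the whole dataset is reproducible given it.
#' @param source_names Labels for the sources (default `caller1..callerR`).
#' @param contig Contig name for generated sites.
#' @param titv_true,titv_false Target Ti/Tv ratios for allele assignment at
#'   true and false-positive positions.
#' @return An object of class `lca_sim`: list with
#'   * `truth` -- tibble of true-variant sites (`chrom`, `pos`, `ref`, `alt`),
#'   * `sites` -- stacked site tibble over all sources, ready for
#'     [pattern_counts()],
#'   * `spec` -- the generating parameters.
#' @export
#' @examples
#' sim <- simulate_call_sets(r = 3, theta = 0.02,
#'                           alpha = c(0.01, 0.02, 0.005),
#'                           beta = c(0.1, 0.2, 0.3),
#'                           total_positions = 5000, seed = 42)
#' nrow(sim$truth)
simulate_call_sets <- function(r = 4, theta = 0.01,
                               alpha = rep(0.005, r), beta = rep(0.2, r),
                               total_positions = 2e5, seed = NULL,
                               source_names = paste0("caller", seq_len(r)),
                               contig = "sim1",
                               titv_true = 2.0, titv_false = 0.5) {
  stopifnot(r >= 1, length(alpha) == r, length(beta) == r,
            total_positions >= 1, length(source_names) == r,
            !anyDuplicated(source_names))
  check_interior(theta, alpha, beta)
  stopifnot(titv_true > 0, titv_false > 0)
  if (!is.null(seed)) set.seed(seed)
  Tt <- as.integer(total_positions)

  is_true <- stats::runif(Tt) < theta
  true_pos <- which(is_true)

  calls <- vector("list", r)
  for (i in seq_len(r)) {
    called <- logical(Tt)
    called[is_true] <- stats::runif(length(true_pos)) < 1 - beta[i]
    false_pos <- which(!is_true)
    called[false_pos] <- stats::runif(length(false_pos)) < alpha[i]
    calls[[i]] <- which(called)
  }

  # alleles drawn once per position, at the class-specific Ti/Tv target
  needed <- sort(unique(c(true_pos, unlist(calls))))
  alleles <- draw_alleles(length(needed),
                          ifelse(needed %in% true_pos, titv_true, titv_false))
  allele_at <- function(pos) {
    idx <- match(pos, needed)
    list(ref = alleles$ref[idx], alt = alleles$alt[idx])
  }

  ta <- allele_at(true_pos)
  truth <- tibble::tibble(chrom = contig, pos = true_pos,
                          ref = ta$ref, alt = ta$alt)
  sites <- purrr::map2_dfr(calls, source_names, function(pos, nm) {
    a <- allele_at(pos)
    tibble::tibble(source = nm, chrom = contig, pos = pos,
                   ref = a$ref, alt = a$alt)
  })
  attr(sites, "source_names") <- source_names
  attr(sites, "contigs") <- contig

  structure(
    list(truth = truth, sites = sites,
         spec = list(r = r, theta = theta, alpha = alpha, beta = beta,
                     total_positions = Tt, seed = seed, contig = contig,
                     titv_true = titv_true, titv_false = titv_false,
                     source_names = source_names)),
    class = "lca_sim"
  )
}

# ref uniform over ACGT; transition with probability titv/(1+titv) (ratio of
# expected counts = titv), otherwise one of the two transversion partners.
draw_alleles <- function(n, titv) {
  bases <- c("A", "C", "G", "T")
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                           C = c("A", "G"), T = c("A", "G"))
  ref <- sample(bases, n, replace = TRUE)
  is_ti <- stats::runif(n) < titv / (1 + titv)
  alt <- character(n)
  alt[is_ti] <- transition_of[ref[is_ti]]
  if (any(!is_ti)) {
    pick <- 1L + (stats::runif(sum(!is_ti)) < 0.5)
    alt[!is_ti] <- mapply(function(b, k) transversions_of[[b]][k],
                          ref[!is_ti], pick)
  }
  list(ref = ref, alt = alt)
}

#' @export
print.lca_sim <- function(x, ...) {
  cat("Simulated call sets: r = ", x$spec$r, ", T = ",
      format(x$spec$total_positions, scientific = FALSE, big.mark = ","),
      ", theta = ", x$spec$theta, "\n", sep = "")
  cat("  true variants: ", nrow(x$truth), "; total assertions: ",
      nrow(x$sites), "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset out as per-source VCF files plus a truth VCF
#'
#' Produces one minimal VCF 4.2 file per source (named `<source>.vcf`) and a
#' `truth.vcf` of the true variants. Reading the files back with
#' [read_vcf_sites()] reproduces the simulated site sets exactly, which makes
#' the files usable as end-to-end pipeline fixtures.
#'
#' @param sim An `lca_sim` object from [simulate_call_sets()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths (sources, then
#'   `truth`), invisibly.
#' @export
write_simulated_vcfs <- function(sim, dir) {
  stopifnot(inherits(sim, "lca_sim"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create directory '", dir, "'", call. = FALSE)

  write_one <- function(tbl, path) {
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=varlca-simulate",
      sprintf("##contig=<ID=%s>", sim$spec$contig),
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            sep = "\t")
    )
    tbl <- tbl[order(tbl$pos), , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                    tbl$chrom, tbl$pos, tbl$ref, tbl$alt)
    writeLines(c(header, body), path)
    path
  }

  src <- sim$spec$source_names
  paths <- vapply(src, function(nm) {
    write_one(sim$sites[sim$sites$source == nm, , drop = FALSE],
              file.path(dir, paste0(nm, ".vcf")))
  }, character(1))
  paths <- c(paths, truth = write_one(sim$truth, file.path(dir, "truth.vcf")))
  invisible(paths)
}
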