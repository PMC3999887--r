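#' Read SNP sites from a VCF file into a site tibble
#'
#' Parses a VCF (plain or bgzip/gzip compressed) and returns one row per SNP
#' assertion: a (chrom, pos, ref, alt) key labelled with the source name.
#' Only single-base substitutions are kept; indels, MNPs and symbolic or
#' non-ACGTN alleles are skipped and tallied. Multiallelic records are split
#' into one row per alternate allele by default, since each ALT allele is a
#' separate assertion about the site.
#'
#' FILTER is ignored by default (callers disagree about what a filter means;
#' the model estimates error rates from agreement instead). `pass_only = TRUE`
#' restricts to records whose FILTER is `PASS` or `.`.
#'
#' @param path Path to a VCF 4.x file (optionally gzip/bgzip compressed).
#' @param name Short label for the evidence source. Defaults to the file name
#'   without extension. Used as the `source` column and in reports.
#' @param pass_only Keep only records with FILTER `PASS` or `.`?
#' @param split_multiallelic Split multiallelic records into one row per ALT
#'   allele? If `FALSE`, multiallelic records are skipped (and tallied).
#'
#' @return A tibble with columns `source`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `qual`, `filter`, one row per SNP assertion, de-duplicated on the
#'   site key. Attributes: `n_skipped` (non-SNP records dropped), `contigs`
#'   (contig names from the header, in header order, if present).
#' @export
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c(
#'   "##fileformat=VCFv4.2",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
#'   "chr1\t100\t.\tA\tG\t50\tPASS\t.",
#'   "chr1\t200\t.\tC\tT,G\t99\tPASS\t."), vcf)
#' read_vcf_sites(vcf, name = "toy")
read_vcf_sites <- function(path, name = NULL,
                           pass_only = FALSE, split_multiallelic = TRUE) {
  if (!file.exists(path)) {
    stop("VCF file not found: ", path, call. = FALSE)
  }
  if (is.null(name)) {
    name <- sub("\\.(vcf|vcf\\.gz|vcf\\.bgz)$", "", basename(path))
  }
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      stop("failed to parse VCF '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  contigs <- stringr::str_match(vcfR::queryMETA(v, element = "contig"),
                                "ID=([^,\\]]+)")[, 2]
  contigs <- contigs[!is.na(contigs)]

  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    warning("VCF '", path, "' contains no variant records", call. = FALSE)
    return(empty_sites(name, contigs))
  }

  pos_num <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos_num)) {
    bad <- which(is.na(pos_num))[1]
    stop("malformed VCF '", path, "': non-numeric POS at record ", bad,
         " (CHROM=", fix$CHROM[bad], ")", call. = FALSE)
  }

  sites <- tibble::tibble(
    source = name,
    chrom  = fix$CHROM,
    pos    = pos_num,
    ref    = toupper(fix$REF),
    alt    = toupper(fix$ALT),
    qual   = suppressWarnings(as.numeric(fix$QUAL)),
    filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER)
  )
  if (pass_only) {
    sites <- dplyr::filter(sites, .data$filter %in% c("PASS", "."))
  }

  n_in <- nrow(sites)
  multi <- stringr::str_detect(sites$alt, stringr::fixed(","))
  if (split_multiallelic) {
    sites <- tidyr::separate_rows(sites, "alt", sep = ",")
  } else {
    sites <- dplyr::filter(sites, !multi)
  }
  snp <- is_snp_key(sites$ref, sites$alt)
  n_skipped <- sum(!snp) + if (split_multiallelic) 0L else sum(multi)
  if (n_skipped > 0) {
    message("source '", name, "': skipped ", n_skipped,
            " non-SNP ALT allele(s) (indel/MNP/symbolic)")
  }
  sites <- dplyr::distinct(
    sites[snp, , drop = FALSE],
    .data$source, .data$chrom, .data$pos, .data$ref, .data$alt,
    .keep_all = TRUE
  )
  if (nrow(sites) == 0 && n_in > 0) {
    warning("source '", name, "': no SNP records survived parsing",
            call. = FALSE)
  }
  attr(sites, "n_skipped") <- n_skipped
  attr(sites, "contigs") <- contigs
  attr(sites, "source_name") <- name
  sites
}

empty_sites <- function(name, contigs = character()) {
  out <- tibble::tibble(
    source = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), qual = numeric(),
    filter = character()
  )
  attr(out, "n_skipped") <- 0L
  attr(out, "contigs") <- contigs
  attr(out, "source_name") <- name
  out
}

is_snp_key <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T", "N") &
    alt %in% c("A", "C", "G", "T", "N") &
    ref != alt
}

#' Read several VCF sources into one stacked site tibble
#'
#' Convenience wrapper around [read_vcf_sites()]: reads each file and binds
#' the rows. Source order (and therefore pattern bit order downstream) is the
#' order of `paths`.
#'
#' @param paths Character vector of VCF paths; names, if present, are used as
#'   source labels.
#' @inheritParams read_vcf_sites
#' @return A site tibble as in [read_vcf_sites()]; the `contigs` attribute is
#'   taken from the first file with contig header lines.
#' @export
read_vcf_sources <- function(paths, pass_only = FALSE,
                             split_multiallelic = TRUE) {
  nm <- names(paths)
  if (is.null(nm)) nm <- rep(NA_character_, length(paths))
  per <- purrr::map2(paths, nm, function(p, n) {
    read_vcf_sites(p, name = if (is.na(n) || n == "") NULL else n,
                   pass_only = pass_only,
                   split_multiallelic = split_multiallelic)
  })
  labels <- purrr::map_chr(per, attr, "source_name")
  if (anyDuplicated(labels)) {
    stop("duplicate source names: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  }
  contigs <- purrr::detect(purrr::map(per, attr, "contigs"),
                           ~ length(.x) > 0) %||% character()
  out <- dplyr::bind_rows(per)
  attr(out, "contigs") <- contigs
  attr(out, "source_names") <- labels
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an integrated call set as a VCF file
#'
#' Emits the calls surviving the posterior cutoff as a VCF 4.2 file. Each
#' record carries two INFO tags: `PPROB` (posterior probability of being a
#' true variant, six decimals) and `SRCS` (comma-joined names of the sources
#' that asserted the site). The fitted parameter estimates, the cutoff, and
#' the total-positions value are recorded as `##varlca_*` header lines so the
#' output documents the run that produced it.
#'
#' Records are sorted by (chrom, pos, alt); chromosome order follows
#' `contig_order` when given (e.g. the first input's header contigs, as
#' returned in the `contigs` attribute of [read_vcf_sites()]), otherwise it
#' is lexicographic.
#'
#' @param calls A tibble of integrated calls from [integrate_calls()]
#'   (columns `chrom`, `pos`, `ref`, `alt`, `posterior`, `sources`).
#' @param path Output file path.
#' @param fit Optional `lca_fit` / `lca_em` object; its point estimates are
#'   echoed into the header.
#' @param cutoff The posterior cutoff that was applied (header echo).
#' @param total_positions The assayable-position count used (header echo).
#' @param contig_order Optional character vector fixing chromosome order.
#' @return `path`, invisibly.
#' @export
write_integrated_vcf <- function(calls, path, fit = NULL, cutoff = NULL,
                                 total_positions = NULL, contig_order = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "posterior") %in% names(calls)))
  if (any(calls$posterior < 0 | calls$posterior > 1)) {
    stop("posterior probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(contig_order)) contig_order <- attr(calls, "contigs")

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=varlca",
    '##INFO=<ID=PPROB,Number=1,Type=Float,Description="Posterior probability that the site is a true variant, from the latent class model">',
    '##INFO=<ID=SRCS,Number=1,Type=String,Description="Comma-separated names of evidence sources asserting this site">'
  )
  if (!is.null(cutoff)) {
    header <- c(header, sprintf("##varlca_cutoff=%s", format(cutoff)))
  }
  if (!is.null(total_positions)) {
    header <- c(header,
                sprintf("##varlca_total_positions=%s",
                        format(total_positions, scientific = FALSE)))
  }
  if (!is.null(fit)) {
    pt <- lca_point(fit)
    header <- c(
      header,
      sprintf("##varlca_theta=%.8g", pt$theta),
      sprintf("##varlca_alpha=%s", paste(sprintf("%.8g", pt$alpha), collapse = ",")),
      sprintf("##varlca_beta=%s", paste(sprintf("%.8g", pt$beta), collapse = ","))
    )
  }
  if (length(contig_order) > 0) {
    header <- c(header,
                sprintf("##contig=<ID=%s>",
                        intersect(contig_order, unique(calls$chrom))))
  }
  header <- c(header,
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))

  calls <- sort_sites(calls, contig_order)
  srcs <- if ("sources" %in% names(calls)) calls$sources else "."
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tPPROB=%.6f;SRCS=%s",
                  calls$chrom, calls$pos, calls$ref, calls$alt,
                  calls$posterior, srcs)

  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write VCF to '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(c(header, body), con)
  if (length(body) == 0) {
    warning("no calls passed the cutoff; wrote a header-only VCF",
            call. = FALSE)
  }
  invisible(path)
}

# Sort by chromosome (given order first, then lexicographic for the rest),
# then position, then alt allele for a stable total order.
sort_sites <- function(x, contig_order = NULL) {
  chroms <- unique(x$chrom)
  lev <- c(intersect(contig_order, chroms),
           sort(setdiff(chroms, contig_order)))
  ord <- order(match(x$chrom, lev), x$pos,
               if ("alt" %in% names(x)) x$alt else NULL)
  x[ord, , drop = FALSE]
}
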