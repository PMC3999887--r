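#' Assign each union site its agreement pattern
#'
#' For every site asserted by at least one source, records which sources
#' called it as a length-`r` bit string (`"0101"`, leftmost bit = first
#' source). Matching is allele-aware by default: two callers reporting
#' different ALT alleles at one position are not corroborating each other.
#' `match_by = "position"` relaxes the key to (chrom, pos), mirroring the
#' agreement tabulations that count "SNP variant positions".
#'
#' @param sites A site tibble (rows from one or more sources stacked; see
#'   [read_vcf_sites()], [read_vcf_sources()]). Must have columns `source`,
#'   `chrom`, `pos`, `ref`, `alt`.
#' @param sources Character vector fixing source order (= pattern bit order).
#'   Defaults to order of first appearance in `sites`; pass explicitly when a
#'   source may be empty.
#' @param match_by `"allele"` (key = chrom, pos, ref, alt) or `"position"`
#'   (key = chrom, pos; ref/alt of the first asserting source are carried).
#' @return A tibble with one row per union site: `chrom`, `pos`, `ref`,
#'   `alt`, `pattern` (bit string), `n_sources`, `sources` (comma-joined
#'   names of asserting sources).
#' @export
site_patterns <- function(sites, sources = NULL,
                          match_by = c("allele", "position")) {
  match_by <- match.arg(match_by)
  sources <- resolve_sources(sites, sources)
  r <- length(sources)
  check_chrom_vocabularies(sites, sources)

  contigs <- attr(sites, "contigs")
  sites <- dplyr::mutate(
    sites, .src_i = match(.data$source, sources)
  )
  if (anyNA(sites$.src_i)) {
    stop("sites contain sources not listed in `sources`", call. = FALSE)
  }
  if (match_by == "allele") {
    grouped <- dplyr::summarise(
      dplyr::group_by(sites, .data$chrom, .data$pos, .data$ref, .data$alt),
      pattern = bits_to_pattern(tabulate(.data$.src_i, nbins = r) > 0),
      n_sources = dplyr::n_distinct(.data$.src_i),
      sources = paste(sources[sort(unique(.data$.src_i))], collapse = ","),
      .groups = "drop"
    )
  } else {
    grouped <- dplyr::summarise(
      dplyr::group_by(sites, .data$chrom, .data$pos),
      ref = .data$ref[which.min(.data$.src_i)],
      alt = .data$alt[which.min(.data$.src_i)],
      pattern = bits_to_pattern(tabulate(.data$.src_i, nbins = r) > 0),
      n_sources = dplyr::n_distinct(.data$.src_i),
      sources = paste(sources[sort(unique(.data$.src_i))], collapse = ","),
      .groups = "drop"
    )
  }
  out <- dplyr::select(grouped, "chrom", "pos", "ref", "alt",
                       "pattern", "n_sources", "sources")
  attr(out, "sources") <- sources
  attr(out, "match_by") <- match_by
  attr(out, "contigs") <- contigs
  out
}

#' Tabulate agreement-pattern counts over all assayable positions
#'
#' Counts, for each of the `2^r` possible agreement patterns over `r`
#' evidence sources, the number of sites exhibiting it. The all-zero pattern
#' (positions called by nobody) cannot be observed in any VCF; its count is
#' `total_positions` minus the union size, which is why `total_positions`
#' (the assayable-region size T) is a required model input. Set it to the
#' size of the callable target, e.g. an exome capture footprint, or genome
#' size for WGS.
#'
#' @inheritParams site_patterns
#' @param total_positions Total number of assayable positions T. Must be at
#'   least the union size.
#' @return A tibble of class `lca_pattern_counts` with columns `pattern` (bit
#'   string over sources, leftmost bit = first source) and `n`, containing
#'   all `2^r` patterns, `sum(n) == total_positions`. Attributes: `sources`,
#'   `r`, `total_positions`, `match_by`.
#' @export
#' @examples
#' sites <- tibble::tibble(
#'   source = c("a", "b"), chrom = "chr1", pos = c(5L, 5L),
#'   ref = "A", alt = "G"
#' )
#' pattern_counts(sites, total_positions = 10)
pattern_counts <- function(sites, total_positions, sources = NULL,
                           match_by = c("allele", "position")) {
  match_by <- match.arg(match_by)
  sources <- resolve_sources(sites, sources)
  r <- length(sources)
  if (r == 1) {
    warning("a single evidence source gives a non-identifiable model; ",
            "error rates cannot be estimated from one rater", call. = FALSE)
  }
  sp <- site_patterns(sites, sources = sources, match_by = match_by)
  n_union <- nrow(sp)
  if (total_positions < n_union) {
    stop("total_positions (", format(total_positions, scientific = FALSE),
         ") is smaller than the union of called sites (", n_union, ")",
         call. = FALSE)
  }
  all_pat <- all_patterns(r)
  observed <- dplyr::count(sp, .data$pattern, name = "n")
  out <- dplyr::left_join(tibble::tibble(pattern = all_pat), observed,
                          by = "pattern")
  out$n[is.na(out$n)] <- 0
  out$n[out$pattern == strrep("0", r)] <- total_positions - n_union
  out <- tibble::new_tibble(out, class = "lca_pattern_counts")
  attr(out, "sources") <- sources
  attr(out, "r") <- r
  attr(out, "total_positions") <- total_positions
  attr(out, "match_by") <- match_by
  out
}

#' Summarise observed agreement between sources
#'
#' A concordance table over the union of called sites: which combinations of
#' sources co-occur, how often, and as what percentage of the union. Only
#' observed (nonzero) patterns are returned; the all-zero pattern never
#' appears since it is not observable.
#'
#' @inheritParams site_patterns
#' @return A tibble with columns `pattern`, `sources`, `n`, `pct`, sorted by
#'   decreasing count; `pct` sums to 100 within rounding.
#' @export
concordance_summary <- function(sites, sources = NULL,
                                match_by = c("allele", "position")) {
  match_by <- match.arg(match_by)
  sources <- resolve_sources(sites, sources)
  sp <- site_patterns(sites, sources = sources, match_by = match_by)
  out <- dplyr::count(sp, .data$pattern, .data$sources, name = "n")
  out <- dplyr::arrange(out, dplyr::desc(.data$n))
  out$pct <- 100 * out$n / sum(out$n)
  out
}

#' @return For `all_patterns()`: character vector of all `2^r` bit strings,
#'   all-zero first, ordered as binary integers with the first source as the
#'   most significant bit.
#' @rdname pattern_bits
#' @export
all_patterns <- function(r) {
  stopifnot(r >= 1)
  if (r > 24) {
    stop("r > 24 sources would enumerate more than 2^24 patterns",
         call. = FALSE)
  }
  vapply(0:(2^r - 1), function(k) {
    bits_to_pattern(as.integer(intToBits(k))[r:1])
  }, character(1))
}

#' Convert between bit-string patterns and 0/1 matrices
#'
#' Agreement patterns are serialized as bit strings (`"0101"`), leftmost bit
#' = first source. `pattern_bits()` expands a vector of patterns to a 0/1
#' matrix (one row per pattern, one column per source); `bits_to_pattern()`
#' collapses a logical/integer vector back to a string.
#'
#' @param pattern Character vector of bit strings (all the same length).
#' @param bits Logical or 0/1 integer vector, one element per source.
#' @param r Number of sources.
#' @return `pattern_bits()`: an integer matrix with one row per pattern.
#' @export
pattern_bits <- function(pattern) {
  stopifnot(length(unique(nchar(pattern))) <= 1)
  m <- do.call(rbind, strsplit(pattern, "", fixed = TRUE))
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m > 1L)) {
    stop("patterns must be strings over {0,1}", call. = FALSE)
  }
  rownames(m) <- pattern
  m
}

#' @rdname pattern_bits
#' @export
bits_to_pattern <- function(bits) {
  paste(as.integer(bits), collapse = "")
}

resolve_sources <- function(sites, sources = NULL) {
  if (is.null(sources)) sources <- attr(sites, "source_names")
  if (is.null(sources)) sources <- unique(sites$source)
  if (length(sources) == 0) {
    stop("no evidence sources found", call. = FALSE)
  }
  if (anyDuplicated(sources)) {
    stop("duplicate source names: ",
         paste(unique(sources[duplicated(sources)]), collapse = ", "),
         call. = FALSE)
  }
  as.character(sources)
}

# Warn loudly when inputs plainly disagree about chromosome naming: either a
# mixture of "chr"-prefixed and bare names, or two sources with disjoint
# vocabularies. No silent normalization is ever applied.
check_chrom_vocabularies <- function(sites, sources) {
  vocab <- split(sites$chrom, factor(sites$source, levels = sources))
  vocab <- lapply(vocab, unique)
  vocab <- vocab[lengths(vocab) > 0]
  if (length(vocab) < 2) return(invisible(NULL))
  prefixed <- vapply(vocab, function(v) any(startsWith(v, "chr")), logical(1))
  bare <- vapply(vocab, function(v) any(!startsWith(v, "chr")), logical(1))
  style_clash <- any(prefixed) && any(bare) && !all(prefixed == bare)
  pairs <- utils::combn(length(vocab), 2)
  disjoint <- any(apply(pairs, 2, function(ij) {
    length(intersect(vocab[[ij[1]]], vocab[[ij[2]]])) == 0
  }))
  if (style_clash || disjoint) {
    desc <- vapply(names(vocab), function(nm) {
      v <- vocab[[nm]]
      paste0(nm, ": {", paste(utils::head(sort(v), 5), collapse = ", "),
             if (length(v) > 5) ", ..." else "", "}")
    }, character(1))
    warning("chromosome naming differs across sources; sites will not match ",
            "across naming styles. Per-source chromosome vocabularies: ",
            paste(desc, collapse = "; "), call. = FALSE)
  }
  invisible(NULL)
}
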