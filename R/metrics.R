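#' Transition/transversion ratio of a SNP set
#'
#' Transitions are purine-purine or pyrimidine-pyrimidine substitutions
#' (A<->G, C<->T); the remaining eight ordered ref/alt pairs are
#' transversions. True human SNP sets show Ti/Tv around 2 (non-coding) to 3
#' (coding), while substitutions drawn uniformly at random give 4/8 = 0.5, so
#' the ratio is a widely used specificity proxy: contamination with random
#' false positives pulls it toward 0.5. It is a proxy, not a confusion-matrix
#' specificity.
#'
#' @param sites A tibble with `ref` and `alt` columns, single-base
#'   substitutions only (rows with N alleles are not classifiable and raise
#'   an error).
#' @return A one-row tibble: `transitions`, `transversions`, `ratio`
#'   (`NA` when there are no transversions; counts are still reported).
#' @export
#' @examples
#' titv_ratio(tibble::tibble(ref = c("A", "C", "A"), alt = c("G", "T", "C")))
titv_ratio <- function(sites) {
  stopifnot(all(c("ref", "alt") %in% names(sites)))
  ok <- is_snp_key(sites$ref, sites$alt) &
    sites$ref %in% c("A", "C", "G", "T") & sites$alt %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    stop(sum(!ok), " record(s) are not classifiable single-base ",
         "substitutions over {A,C,G,T}", call. = FALSE)
  }
  ti <- is_transition(sites$ref, sites$alt)
  n_ti <- sum(ti)
  n_tv <- sum(!ti)
  tibble::tibble(
    transitions = n_ti,
    transversions = n_tv,
    ratio = if (n_tv == 0) NA_real_ else round(n_ti / n_tv, 4)
  )
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Sensitivity of a call set against a truth set
#'
#' The percentage of truth sites recovered by the call set,
#' `100 * |callset intersect truth| / |truth|`. Both sets must be keyed the
#' same way (same matching mode).
#'
#' @param callset,truth Tibbles of sites with columns `chrom`, `pos`, `ref`,
#'   `alt` (`ref`/`alt` ignored when `match_by = "position"`).
#' @param match_by Key on alleles (`"allele"`) or positions (`"position"`).
#' @return A single percentage in \[0, 100\].
#' @export
sensitivity_vs_truth <- function(callset, truth,
                                 match_by = c("allele", "position")) {
  match_by <- match.arg(match_by)
  kt <- site_key(truth, match_by)
  if (length(kt) == 0) stop("truth set is empty", call. = FALSE)
  kc <- site_key(callset, match_by)
  100 * sum(kt %in% kc) / length(kt)
}

#' Fraction of a call set found in a database set
#'
#' `100 * |callset intersect db| / |callset|`: the share of calls already
#' catalogued in a database such as COSMIC or dbSNP, used as a specificity
#' proxy for somatic call sets.
#'
#' @param callset,db Site tibbles as in [sensitivity_vs_truth()].
#' @inheritParams sensitivity_vs_truth
#' @return A single percentage in \[0, 100\].
#' @export
fraction_in_database <- function(callset, db,
                                 match_by = c("allele", "position")) {
  match_by <- match.arg(match_by)
  kc <- site_key(callset, match_by)
  if (length(kc) == 0) stop("call set is empty", call. = FALSE)
  kd <- site_key(db, match_by)
  100 * sum(kc %in% kd) / length(kc)
}

site_key <- function(x, match_by = "allele") {
  if (nrow(x) == 0) return(character())
  if (match_by == "allele") {
    unique(paste(x$chrom, x$pos, x$ref, x$alt, sep = ":"))
  } else {
    unique(paste(x$chrom, x$pos, sep = ":"))
  }
}

#' Detection-error-tradeoff curve over posterior cutoffs
#'
#' Sweeps the posterior cutoff and reports, for the integrated call set at
#' each value: the number of calls, sensitivity against a truth set, the
#' Ti/Tv ratio, and precision (percent of calls that are truth sites). Since
#' call sets at increasing cutoffs are nested, the call count and sensitivity
#' are non-increasing in the cutoff. Cutoff 0 reproduces the union of the
#' input call sets (maximal sensitivity); cutoff 1 approaches the
#' intersection-like maximal-specificity end.
#'
#' @inheritParams integrate_calls
#' @param truth Tibble of truth sites (e.g. from [simulate_call_sets()]).
#' @param cutoffs Increasing vector of posterior cutoffs.
#' @param bed Optional region table from [read_bed()]; when given, the curve
#'   is computed on the sites inside the regions only.
#' @return A tibble with one row per cutoff: `cutoff`, `n_calls`,
#'   `sensitivity`, `titv`, `precision`.
#' @export
det_curve <- function(sites, fit, truth, cutoffs = c(0, 0.5, 0.8, 0.9, 0.99),
                      sources = NULL, match_by = c("allele", "position"),
                      bed = NULL) {
  match_by <- match.arg(match_by)
  stopifnot(!is.unsorted(cutoffs))
  all_calls <- integrate_calls(sites, fit, cutoff = 0, sources = sources,
                               match_by = match_by)
  if (!is.null(bed)) {
    all_calls <- all_calls[in_regions(all_calls, bed), , drop = FALSE]
    truth <- truth[in_regions(truth, bed), , drop = FALSE]
  }
  tk <- site_key(truth, match_by)
  purrr::map_dfr(cutoffs, function(cc) {
    calls <- all_calls[all_calls$posterior >= cc - 1e-9, , drop = FALSE]
    ck <- site_key(calls, match_by)
    tibble::tibble(
      cutoff = cc,
      n_calls = nrow(calls),
      sensitivity = 100 * sum(tk %in% ck) / length(tk),
      titv = if (nrow(calls) > 0) titv_ratio(calls)$ratio else NA_real_,
      precision = if (length(ck) > 0) 100 * sum(ck %in% tk) / length(ck)
                  else NA_real_
    )
  })
}

#' Read a BED file of regions
#'
#' Reads the first three columns of a BED file (0-based, half-open
#' intervals). Used to stratify metrics by region membership, e.g. coding vs
#' non-coding.
#'
#' @param path BED file path (plain text; track/browser/comment lines are
#'   skipped).
#' @return A tibble with columns `chrom`, `start` (0-based inclusive), `end`
#'   (0-based exclusive).
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  parts <- stringr::str_split_fixed(lines, "\t", 4)
  out <- tibble::tibble(
    chrom = parts[, 1],
    start = as.integer(parts[, 2]),
    end = as.integer(parts[, 3])
  )
  if (anyNA(out$start) || anyNA(out$end) || any(out$end < out$start)) {
    stop("malformed BED intervals in ", path, call. = FALSE)
  }
  out
}

#' Test which sites fall inside BED regions
#'
#' A 1-based VCF position `pos` lies in a BED interval `[start, end)` iff
#' `start < pos <= end` after converting conventions (the BED interval covers
#' 1-based positions `start + 1` to `end`). Intervals are merged per
#' chromosome before a sorted-interval lookup.
#'
#' @param sites Tibble with `chrom` and `pos` (1-based).
#' @param bed Region tibble from [read_bed()].
#' @return Logical vector, one element per row of `sites`.
#' @export
in_regions <- function(sites, bed) {
  out <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    iv <- bed[bed$chrom == ch, , drop = FALSE]
    sel <- sites$chrom == ch
    if (nrow(iv) == 0) next
    iv <- merge_intervals(iv$start, iv$end)
    p0 <- sites$pos[sel] - 1L  # 0-based point
    idx <- findInterval(p0, iv$start)
    out[sel] <- idx > 0 & p0 < iv$end[pmax(idx, 1L)]
  }
  out
}

merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  outs <- c()
  oute <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(outs, ms), end = c(oute, me))
}
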