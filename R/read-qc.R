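#' Length- and budget-bounded read subsampling
#'
#' Reproduces the raw-data subsampling strategy: walk the reads in input
#' order, keep those within the length bounds, and stop once the kept
#' cumulative length reaches the basepair budget (the read that crosses the
#' budget is included). Deterministic; an optional shuffle seed randomises
#' the visiting order reproducibly.
#'
#' @param reads data.frame with a `sequence` column, or a numeric vector of
#'   read lengths.
#' @param params a [sample_params()].
#' @param shuffle_seed if non-`NULL`, reads are visited in a seeded random
#'   order instead of input order.
#' @return the selected subset of `reads` (same type as the input), in
#'   visiting order. Warns if the budget could not be met.
#' @export
sample_reads <- function(reads, params = sample_params(), shuffle_seed = NULL) {
  lens <- if (is.data.frame(reads)) nchar(reads$sequence) else as.numeric(reads)
  idx <- seq_along(lens)
  if (!is.null(shuffle_seed)) {
    set.seed(shuffle_seed)
    idx <- sample(idx)
  }
  sel <- integer(0)
  cum <- 0
  for (i in idx) {
    if (cum >= params$budget) break
    if (lens[i] >= params$min_len && lens[i] <= params$max_len) {
      sel <- c(sel, i)
      cum <- cum + lens[i]
    }
  }
  if (cum < params$budget) warnf("budget unmet: selected %s bp of %s requested",
                                 format_bp(cum), format_bp(params$budget))
  if (is.data.frame(reads)) reads[sel, , drop = FALSE] else reads[sel]
}

#' Parameters for [sample_reads()]
#'
#' Defaults are the CLR subsampling settings used for the assembly: reads
#' between 10 and 40 kbp, to a total of 70 Gbp (~70x of a ~1 Gbp genome).
#'
#' @param min_len,max_len read length bounds (bp).
#' @param budget total bp to select.
#' @return a list of class `"sample_params"`.
#' @export
sample_params <- function(min_len = 10000, max_len = 40000, budget = 70e9) {
  stopifnot(min_len <= max_len, budget >= 0)
  structure(list(min_len = min_len, max_len = max_len, budget = budget),
            class = "sample_params")
}

#' Parameters for [scrub_reads()]
#'
#' Defaults follow the published scrubbing configuration: a read is
#' low-coverage when bases at coverage <= 3 make up >= 40% of its length.
#'
#' @param min_coverage coverage threshold (a base is "low" when its overlap
#'   coverage is <= this value).
#' @param min_low_fraction fraction of low bases at which a read is removed.
#' @return a list of class `"scrub_params"`.
#' @export
scrub_params <- function(min_coverage = 3, min_low_fraction = 0.4) {
  stopifnot(min_coverage >= 0, min_low_fraction > 0, min_low_fraction <= 1)
  structure(list(min_coverage = min_coverage,
                 min_low_fraction = min_low_fraction),
            class = "scrub_params")
}

#' Filter all-vs-all overlaps before scrubbing
#'
#' Drops overlaps whose aligned query span is shorter than
#' `min_overlap_len`, and "internal matches": one read aligned over its
#' full length (to within `end_tolerance` bp) strictly inside the other
#' read, with the containing read's alignment boundary more than
#' `end_tolerance` bp from both of its ends.
#'
#' @param overlaps overlap data.frame (see [read_overlaps_table()]).
#' @param min_overlap_len minimum aligned length in bp (default 2,000).
#' @param end_tolerance bp of slack when testing containment (default 50).
#' @return the kept overlaps.
#' @export
filter_overlaps <- function(overlaps, min_overlap_len = 2000,
                            end_tolerance = 50) {
  if (nrow(overlaps) == 0) return(overlaps)
  qspan <- overlaps$qend - overlaps$qstart + 1
  tspan <- overlaps$tend - overlaps$tstart + 1
  short <- qspan < min_overlap_len | tspan < min_overlap_len
  q_full <- overlaps$qstart - 1 <= end_tolerance &
    overlaps$qlen - overlaps$qend <= end_tolerance
  t_interior <- overlaps$tstart - 1 > end_tolerance &
    overlaps$tlen - overlaps$tend > end_tolerance
  t_full <- overlaps$tstart - 1 <= end_tolerance &
    overlaps$tlen - overlaps$tend <= end_tolerance
  q_interior <- overlaps$qstart - 1 > end_tolerance &
    overlaps$qlen - overlaps$qend > end_tolerance
  internal <- (q_full & t_interior) | (t_full & q_interior)
  overlaps[!(short | internal), , drop = FALSE]
}

#' Per-base overlap coverage of one read
#'
#' Counts, at every base of the read, the overlaps whose aligned span
#' covers that base. When `read` is given, spans are taken from both roles
#' (rows where the read is the query and rows where it is the target);
#' otherwise every row's query span is assumed to refer to the read.
#' Duplicated overlap rows count multiply, by definition.
#'
#' @param read_length read length in bp.
#' @param overlaps overlap data.frame touching the read.
#' @param read read name used to pick the relevant span of each row.
#' @return integer vector of length `read_length`.
#' @export
coverage_profile <- function(read_length, overlaps, read = NULL) {
  if (is.null(read)) {
    starts <- overlaps$qstart
    ends <- overlaps$qend
  } else {
    isq <- overlaps$qname == read
    ist <- overlaps$tname == read
    starts <- c(overlaps$qstart[isq], overlaps$tstart[ist])
    ends <- c(overlaps$qend[isq], overlaps$tend[ist])
  }
  if (length(starts) == 0) return(integer(read_length))
  if (any(starts < 1 | ends > read_length | starts > ends))
    abort("overlap span outside read bounds (read length %d)", read_length)
  delta <- integer(read_length + 1)
  tab_s <- table(starts)
  tab_e <- table(ends)
  delta[as.integer(names(tab_s))] <- as.integer(tab_s)
  ends_idx <- as.integer(names(tab_e)) + 1L
  delta[ends_idx] <- delta[ends_idx] - as.integer(tab_e)
  cumsum(delta)[seq_len(read_length)]
}

#' Classify reads as kept, low-coverage or chimeric from overlap coverage
#'
#' Implements coverage-based scrubbing of raw long reads: a read is
#' `removed_low_coverage` when bases at coverage <= `min_coverage` make up
#' at least `min_low_fraction` of its length, and `removed_chimeric` when a
#' maximal low-coverage run is strictly interior, i.e. flanked on both
#' sides by runs above the coverage threshold (the signature of a chimeric
#' junction). Chimeric takes precedence in reporting.
#'
#' @param reads data.frame with `id` and `sequence`, or a named numeric
#'   vector of read lengths.
#' @param overlaps overlap data.frame, already passed through
#'   [filter_overlaps()].
#' @param params a [scrub_params()].
#' @return data.frame with columns `read`, `length`, `low_fraction`,
#'   `classification`.
#' @export
scrub_reads <- function(reads, overlaps, params = scrub_params()) {
  if (is.data.frame(reads)) {
    lens <- stats::setNames(nchar(reads$sequence), reads$id)
  } else lens <- reads
  missing <- setdiff(unique(c(overlaps$qname, overlaps$tname)), names(lens))
  if (length(missing) > 0)
    abort("overlap references read %s absent from the read set", missing[1])
  n <- length(lens)
  cls <- character(n)
  lowfrac <- numeric(n)
  by_q <- split(seq_len(nrow(overlaps)), overlaps$qname)
  by_t <- split(seq_len(nrow(overlaps)), overlaps$tname)
  for (i in seq_len(n)) {
    nm <- names(lens)[i]
    rows <- overlaps[c(by_q[[nm]], by_t[[nm]]), , drop = FALSE]
    cov <- coverage_profile(lens[[i]], rows, read = nm)
    low <- cov <= params$min_coverage
    lowfrac[i] <- mean(low)
    runs <- rle(low)
    interior <- runs$values & seq_along(runs$values) > 1 &
      seq_along(runs$values) < length(runs$values)
    if (any(interior)) {
      cls[i] <- "removed_chimeric"
    } else if (lowfrac[i] >= params$min_low_fraction) {
      cls[i] <- "removed_low_coverage"
    } else cls[i] <- "kept"
  }
  data.frame(read = names(lens), length = as.numeric(lens),
             low_fraction = lowfrac, classification = cls,
             stringsAsFactors = FALSE)
}
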