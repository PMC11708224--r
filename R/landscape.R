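#' Windowed feature-density track
#'
#' Tallies features in sliding windows along each chromosome: a new window
#' of `window` bp every `step` bp, starting at 0 and truncated at the
#' chromosome end; every window with a start before the chromosome end is
#' emitted. A feature is counted in a window iff its midpoint (0-based)
#' falls in the half-open window `[win_start, win_end)`, so for
#' non-overlapping windows (`step == window`) each feature is counted
#' exactly once. Window coordinates are reported BED-style (0-based
#' half-open).
#'
#' @param features feature data.frame (1-based inclusive coordinates).
#' @param chrom_lengths named chromosome lengths in bp.
#' @param window window size in bp (default 250,000).
#' @param step step between window starts in bp (default 100,000).
#' @return data.frame `chrom`, `win_start`, `win_end`, `count`.
#' @export
windowed_density <- function(features, chrom_lengths, window = 250000,
                             step = 100000) {
  stopifnot(step > 0, step <= window)
  bad <- !features$seqid %in% names(chrom_lengths)
  if (any(bad)) abort("feature on unknown chromosome %s",
                      features$seqid[bad][1])
  over <- features$end > chrom_lengths[features$seqid]
  if (any(over)) abort("feature %s extends beyond chromosome %s (%d > %d)",
                       gff_attr(features[over, , drop = FALSE], "ID")[1],
                       features$seqid[over][1], features$end[over][1],
                       chrom_lengths[[features$seqid[over][1]]])
  mid0 <- floor((features$start - 1 + features$end) / 2)
  out <- lapply(names(chrom_lengths), function(chrom) {
    L <- chrom_lengths[[chrom]]
    starts <- seq(0, L - 1, by = step)
    ends <- pmin(starts + window, L)
    m <- mid0[features$seqid == chrom]
    counts <- vapply(seq_along(starts), function(i)
      sum(m >= starts[i] & m < ends[i]), numeric(1))
    data.frame(chrom = chrom, win_start = starts, win_end = ends,
               count = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Kimura 2-parameter divergence of an aligned pair
#'
#' Over the ungapped, unambiguous columns (both bases in A/C/G/T): `P` is
#' the transition proportion, `Q` the transversion proportion, and
#' `K = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]`. Gap and `N` columns are
#' excluded from the denominators.
#'
#' @param aligned_copy,aligned_consensus equal-length aligned strings
#'   (DNA plus `-`).
#' @return named numeric vector `c(P = , Q = , K = )`.
#' @export
kimura_k2p <- function(aligned_copy, aligned_consensus) {
  a <- strsplit(toupper(aligned_copy), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(aligned_consensus), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) abort("aligned strings differ in length")
  dna <- c("A", "C", "G", "T")
  use <- a %in% dna & b %in% dna
  n <- sum(use)
  if (n == 0) abort("no ungapped unambiguous columns")
  a <- a[use]; b <- b[use]
  diffs <- a != b
  purine <- c("A", "G")
  ts <- diffs & ((a %in% purine) == (b %in% purine))
  P <- sum(ts) / n
  Q <- sum(diffs & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    abort("saturation: Kimura distance undefined (P = %.3f, Q = %.3f)", P, Q)
  c(P = P, Q = Q, K = -0.5 * log(w1 * sqrt(w2)))
}

#' Repeat landscape: genome coverage per divergence bin and repeat class
#'
#' Each repeat copy contributes its ungapped aligned basepairs to the
#' 1%-wide Kimura-divergence bin `floor(100 K)` of its class. Saturated
#' pairs (Kimura distance undefined) are skipped; their count is attached
#' as the `"skipped"` attribute.
#'
#' @param pairs data.frame with `aligned_copy`, `aligned_consensus`,
#'   `class_label` (e.g. from [generate_repeat_copies()]).
#' @param genome_size genome size in bp used for the coverage denominator.
#' @return data.frame `bin_lower_pct`, `class_label`, `bp`,
#'   `genome_fraction`, ordered by bin then class.
#' @export
repeat_landscape <- function(pairs, genome_size) {
  stopifnot(genome_size > 0)
  n <- nrow(pairs)
  bin <- integer(n)
  bp <- numeric(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    pqk <- tryCatch(kimura_k2p(pairs$aligned_copy[i],
                               pairs$aligned_consensus[i]),
                    error = function(e) NULL)
    if (is.null(pqk)) next
    ok[i] <- TRUE
    bin[i] <- floor(100 * pqk[["K"]])
    a <- strsplit(toupper(pairs$aligned_copy[i]), "", fixed = TRUE)[[1]]
    b <- strsplit(toupper(pairs$aligned_consensus[i]), "", fixed = TRUE)[[1]]
    dna <- c("A", "C", "G", "T")
    bp[i] <- sum(a %in% dna & b %in% dna)
  }
  agg <- stats::aggregate(
    bp ~ bin_lower_pct + class_label,
    data = data.frame(bin_lower_pct = bin[ok],
                      class_label = pairs$class_label[ok], bp = bp[ok],
                      stringsAsFactors = FALSE),
    FUN = sum)
  agg <- agg[order(agg$bin_lower_pct, agg$class_label), , drop = FALSE]
  agg$genome_fraction <- agg$bp / genome_size
  rownames(agg) <- NULL
  structure(agg, skipped = sum(!ok))
}
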