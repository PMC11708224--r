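#' Nx / Lx contiguity statistics
#'
#' Standard definitions: sort lengths descending; `Nx` is the length of the
#' first element at which the cumulative sum reaches `x`% of the total, and
#' `Lx` is its 1-based rank. Ties resolve by the sorted order.
#'
#' @param lengths positive scaffold/contig/read lengths.
#' @param x percentage threshold (50 for N50/L50).
#' @return named numeric vector `c(Nx = , Lx = )`.
#' @export
nx_lx <- function(lengths, x = 50) {
  if (length(lengths) == 0) abort("empty length list")
  if (any(lengths <= 0)) abort("lengths must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  k <- which(cumsum(s) >= x / 100 * sum(s))[1]
  c(Nx = s[k], Lx = k)
}

#' Summarize an assembly: contiguity, size, chromosome content
#'
#' Scaffold lengths include gap (N) bases. The percentage of the assembly
#' in chromosome-level scaffolds is reported to 2 decimals, rounded
#' half-up, matching genome-report convention. Chromosome-level scaffolds
#' are designated by an explicit id list, not a length cutoff.
#'
#' @param scaffolds named numeric vector of scaffold lengths, or a
#'   data.frame with `id` and `sequence`.
#' @param chromosome_ids character vector of scaffold ids designated as
#'   chromosomes (subset of the scaffold ids).
#' @return list of class `"assembly_summary"`: `n_scaffolds`,
#'   `total_length`, `nx` (rows N50/N90 with Nx and Lx), `largest`,
#'   `n_chromosome_scaffolds`, `chromosome_length`, `pct_in_chromosomes`.
#' @export
summarize_assembly <- function(scaffolds, chromosome_ids = character()) {
  if (is.data.frame(scaffolds)) {
    lens <- stats::setNames(nchar(scaffolds$sequence), scaffolds$id)
  } else lens <- scaffolds
  unknown <- setdiff(chromosome_ids, names(lens))
  if (length(unknown) > 0) abort("unknown chromosome id %s", unknown[1])
  total <- sum(lens)
  chrlen <- sum(lens[chromosome_ids])
  nx <- t(vapply(c(50, 90), function(x) nx_lx(lens, x), numeric(2)))
  rownames(nx) <- c("N50", "N90")
  structure(list(
    n_scaffolds = length(lens), total_length = total, nx = nx,
    largest = max(lens),
    n_chromosome_scaffolds = length(chromosome_ids),
    chromosome_length = chrlen,
    pct_in_chromosomes = round_half_up(100 * chrlen / total, 2)),
    class = "assembly_summary")
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Number of scaffolds\t%d\n",
    "Total scaffold length\t%s bp\n",
    "Scaffold N50\t%s bp (L50 %d)\n",
    "Largest scaffold\t%s bp\n",
    "Chromosome-level scaffolds\t%d\n",
    "Total bases in chromosomes\t%s bp\n",
    "Percentage of assembly in chromosomes\t%.2f%%\n"),
    x$n_scaffolds, format(x$total_length, big.mark = ","),
    format(x$nx["N50", "Nx"], big.mark = ","), x$nx["N50", "Lx"],
    format(x$largest, big.mark = ","), x$n_chromosome_scaffolds,
    format(x$chromosome_length, big.mark = ","), x$pct_in_chromosomes))
  invisible(x)
}

#' BUSCO completeness percentages
#'
#' Validates the BUSCO identities (`complete = single + duplicated`;
#' `complete + fragmented + missing = total`) and reports each class as a
#' percentage of the total ortholog set, to 1 decimal, rounded half-up.
#'
#' @param complete,single,duplicated,fragmented,missing,total non-negative
#'   integer BUSCO counts.
#' @return named numeric vector of percentages for complete, single,
#'   duplicated, fragmented, missing.
#' @export
busco_percentages <- function(complete, single, duplicated, fragmented,
                              missing, total) {
  counts <- c(complete, single, duplicated, fragmented, missing, total)
  if (any(counts < 0) || any(counts != floor(counts)))
    abort("BUSCO counts must be non-negative integers")
  if (complete != single + duplicated)
    abort("BUSCO identity violated: complete (%d) != single + duplicated (%d)",
          complete, single + duplicated)
  if (complete + fragmented + missing != total)
    abort("BUSCO identity violated: complete + fragmented + missing (%d) != total (%d)",
          complete + fragmented + missing, total)
  if (total == 0) abort("BUSCO total must be positive")
  round_half_up(100 * c(complete = complete, single = single,
                        duplicated = duplicated, fragmented = fragmented,
                        missing = missing) / total, 1)
}

#' Summarize a raw read set
#'
#' @param lengths read lengths in bp.
#' @param thresholds lengths for the "reads longer than" counts (default
#'   20 kbp and 50 kbp).
#' @return list of class `"read_set_summary"`: `count`, `total`, `mean`
#'   (2 decimals, half-up), `n50`, `n_over` (named counts).
#' @export
summarize_reads <- function(lengths, thresholds = c(20000, 50000)) {
  if (length(lengths) == 0) abort("empty length list")
  n_over <- vapply(thresholds, function(t) sum(lengths > t), numeric(1))
  names(n_over) <- sprintf(">%s bp", format(thresholds, big.mark = ",",
                                            trim = TRUE))
  structure(list(count = length(lengths), total = sum(as.numeric(lengths)),
                 mean = round_half_up(sum(as.numeric(lengths)) / length(lengths), 2),
                 n50 = unname(nx_lx(lengths, 50)["Nx"]),
                 n_over = n_over),
            class = "read_set_summary")
}

#' Mean read length from reported totals
#'
#' Convenience for recomputing a reported mean directly from a read count
#' and total basepair yield, with report-style rounding (2 decimals,
#' half-up).
#'
#' @param total_bp total basepairs.
#' @param count number of reads.
#' @return mean read length in bp.
#' @export
mean_length_from_totals <- function(total_bp, count) {
  round_half_up(total_bp / count, 2)
}

#' @export
print.read_set_summary <- function(x, ...) {
  cat(sprintf("Read count\t%s\nTotal length\t%s bp\nMean length\t%.2f bp\nN50 length\t%s bp\n",
              format(x$count, big.mark = ","), format(x$total, big.mark = ","),
              x$mean, format(x$n50, big.mark = ",")))
  for (i in seq_along(x$n_over))
    cat(sprintf("Reads %s\t%s\n", names(x$n_over)[i],
                format(x$n_over[i], big.mark = ",")))
  invisible(x)
}
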