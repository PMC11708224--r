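#' Locate k-mer clumps ("klumps") of a reference within query sequences
#'
#' A match is a query position whose k-mer occurs in the reference k-mer
#' set; matching is over canonical (strand-collapsed) k-mers, so both
#' strands of the query are covered and the result is invariant under
#' reverse-complementing the reference. Consecutive matches on a query
#' whose starts lie within `range` bp are grouped into one klump; klumps
#' with fewer than `min_kmers` matches are discarded. The klump span runs
#' from the first match start to the last match start plus `ksize`.
#' Defaults mirror the locus-validation settings used for AFGP screening
#' (k = 17, at least 20 k-mers, 1,000 bp grouping range).
#'
#' @param query_seqs named character vector of query sequences, or a
#'   data.frame with `id` and `sequence`.
#' @param reference_seq reference DNA string.
#' @param ksize k-mer size (>= 3).
#' @param min_kmers minimum matches per reported klump.
#' @param range maximum bp between consecutive match starts in one klump.
#' @return data.frame `query_id`, `start`, `end` (1-based inclusive),
#'   `kmer_count`.
#' @export
find_klumps <- function(query_seqs, reference_seq, ksize = 17,
                        min_kmers = 20, range = 1000) {
  stopifnot(ksize >= 3, min_kmers >= 1, range >= 1)
  if (nchar(reference_seq) < ksize)
    abort("reference (%d bp) shorter than ksize %d", nchar(reference_seq), ksize)
  if (is.data.frame(query_seqs)) {
    query_seqs <- stats::setNames(query_seqs$sequence, query_seqs$id)
  }
  ref_set <- unique(canonical_kmers(toupper(reference_seq), ksize))
  out <- list()
  for (qid in names(query_seqs)) {
    q <- toupper(query_seqs[[qid]])
    if (nchar(q) < ksize) next
    km <- canonical_kmers(q, ksize)
    hit <- which(km %in% ref_set)
    if (length(hit) == 0) next
    grp <- cumsum(c(1, diff(hit) > range))
    for (g in unique(grp)) {
      pos <- hit[grp == g]
      if (length(pos) < min_kmers) next
      out[[length(out) + 1]] <- data.frame(
        query_id = qid, start = pos[1], end = pos[length(pos)] + ksize - 1,
        kmer_count = length(pos), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(query_id = character(), start = integer(),
                      end = integer(), kmer_count = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

canonical_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1
  fwd <- substring(seq, seq_len(n), seq_len(n) + k - 1)
  rc <- substring(revcomp(seq), seq_len(n), seq_len(n) + k - 1)
  rev_for_pos <- rc[n:1]   # k-mer at fwd position i is rc position n-i+1
  pmin(fwd, rev_for_pos)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Check a coding sequence for pseudogenization signatures
#'
#' Translates the CDS in frame and reports the first integrity problem:
#' `frameshift` when the length is not a multiple of 3, `premature_stop`
#' when a stop codon occurs before the final codon, `incomplete` when the
#' sequence is too short to hold a codon, otherwise `intact`. A missing
#' ATG start codon is noted in the details but does not change the status.
#'
#' @param cds_seq CDS DNA string (A/C/G/T/N).
#' @param gene_id optional id echoed in the report.
#' @return data.frame `gene_id`, `status`, `details`.
#' @export
check_gene_integrity <- function(cds_seq, gene_id = NA_character_) {
  s <- toupper(cds_seq)
  if (grepl("[^ACGTN]", s)) abort("non-ACGTN character in CDS")
  report <- function(status, details) {
    data.frame(gene_id = gene_id, status = status, details = details,
               stringsAsFactors = FALSE)
  }
  if (nchar(s) < 3) return(report("incomplete", "shorter than one codon"))
  if (nchar(s) %% 3 != 0)
    return(report("frameshift", sprintf("length %d mod 3 = %d", nchar(s),
                                        nchar(s) %% 3)))
  ncod <- nchar(s) / 3
  codons <- substring(s, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
  stops <- which(codons %in% STOP_CODONS)
  premature <- stops[stops < ncod]
  start_note <- if (codons[1] != "ATG") "; no ATG start codon" else ""
  if (length(premature) > 0)
    return(report("premature_stop",
                  sprintf("stop codon %s at codon %d of %d%s",
                          codons[premature[1]], premature[1], ncod,
                          start_note)))
  report("intact", sprintf("%d codons%s%s", ncod,
                           if (length(stops) == 0) "; no terminal stop" else "",
                           start_note))
}
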