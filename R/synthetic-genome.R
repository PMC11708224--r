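#' Specification for a synthetic notothenioid-like genome
#'
#' The generator emulates the qualitative architecture of notothenioid
#' chromosomes: protein-coding genes concentrated in chromosome centers and
#' interspersed repeats enriched toward the telomeric ends. Gene midpoints
#' are drawn from a symmetric Beta(1 + bias, 1 + bias) on relative position
#' (bias 0 reduces to uniform); repeat midpoints from an equal mixture of
#' Beta(1, 1 + bias) and Beta(1 + bias, 1).
#'
#' @param n_chromosomes number of chromosomes (default 23, the karyotype
#'   modelled throughout the package).
#' @param chrom_length_range min/max chromosome length in bp.
#' @param gene_count_per_chrom genes per chromosome (default 87, i.e. about
#'   2,000 genes genome-wide at 23 chromosomes).
#' @param gene_center_bias non-negative center-bias strength for genes.
#' @param repeat_terminal_bias non-negative terminal-bias strength for
#'   repeats.
#' @param repeat_count_per_chrom repeat features per chromosome.
#' @param gene_length_range,repeat_length_range feature length ranges (bp).
#' @param seed integer seed; all generator randomness derives from it.
#' @return a list of class `"genome_spec"`.
#' @export
genome_spec <- function(n_chromosomes = 23,
                        chrom_length_range = c(400e3, 600e3),
                        gene_count_per_chrom = 87,
                        gene_center_bias = 2,
                        repeat_terminal_bias = 3,
                        repeat_count_per_chrom = 120,
                        gene_length_range = c(500, 2000),
                        repeat_length_range = c(200, 1500),
                        seed = 1) {
  stopifnot(is_count(n_chromosomes), n_chromosomes >= 1,
            length(chrom_length_range) == 2, all(chrom_length_range > 0),
            is_count(gene_count_per_chrom),
            is.finite(gene_center_bias), gene_center_bias >= 0,
            is.finite(repeat_terminal_bias), repeat_terminal_bias >= 0)
  structure(list(n_chromosomes = n_chromosomes,
                 chrom_length_range = as.numeric(chrom_length_range),
                 gene_count_per_chrom = gene_count_per_chrom,
                 gene_center_bias = gene_center_bias,
                 repeat_terminal_bias = repeat_terminal_bias,
                 repeat_count_per_chrom = repeat_count_per_chrom,
                 gene_length_range = as.numeric(gene_length_range),
                 repeat_length_range = as.numeric(repeat_length_range),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic genome with gene and repeat annotation
#'
#' Deterministic for a fixed spec (same seed gives byte-identical FASTA and
#' GFF3 output). Features are non-overlapping within each feature type;
#' overlaps arising from biased placement are resolved by a minimal
#' left-to-right shift.
#'
#' @param spec a [genome_spec()].
#' @param with_sequence generate chromosome sequences (set `FALSE` for
#'   annotation-only work such as synteny simulations; annotation draws are
#'   unaffected).
#' @return a list of class `"synthetic_genome"` with elements `seqs` (named
#'   character or `NULL`), `lengths` (named numeric), `genes` and `repeats`
#'   (feature data.frames as in [read_gff3()]), and `spec`.
#' @export
generate_genome <- function(spec, with_sequence = TRUE) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  nchr <- spec$n_chromosomes
  chroms <- sprintf("chr%02d", seq_len(nchr))
  lens <- round(stats::runif(nchr, spec$chrom_length_range[1],
                             spec$chrom_length_range[2]))
  names(lens) <- chroms
  genes <- vector("list", nchr)
  repeats <- vector("list", nchr)
  rep_classes <- c("DNA", "LINE", "SINE", "LTR", "Unclassified")
  for (i in seq_len(nchr)) {
    g <- place_features(lens[i], spec$gene_count_per_chrom,
                        spec$gene_length_range,
                        midpoint_sampler_center(spec$gene_center_bias))
    genes[[i]] <- data.frame(
      seqid = chroms[i], source = "notocraft", type = "gene",
      start = g$start, end = g$end, score = ".",
      strand = sample(c("+", "-"), nrow(g), replace = TRUE), phase = ".",
      attributes = sprintf("ID=gene_%s_%03d", chroms[i], seq_len(nrow(g))),
      stringsAsFactors = FALSE)
    r <- place_features(lens[i], spec$repeat_count_per_chrom,
                        spec$repeat_length_range,
                        midpoint_sampler_terminal(spec$repeat_terminal_bias))
    cls <- sample(rep_classes, nrow(r), replace = TRUE,
                  prob = c(0.35, 0.2, 0.05, 0.15, 0.25))
    repeats[[i]] <- data.frame(
      seqid = chroms[i], source = "notocraft", type = "dispersed_repeat",
      start = r$start, end = r$end, score = ".",
      strand = rep(".", nrow(r)), phase = ".",
      attributes = sprintf("ID=rep_%s_%03d;class=%s", chroms[i],
                           seq_len(nrow(r)), cls),
      stringsAsFactors = FALSE)
  }
  seqs <- NULL
  if (with_sequence) {
    seqs <- vapply(lens, random_dna, character(1))
    names(seqs) <- chroms
  }
  structure(list(seqs = seqs, lengths = lens,
                 genes = do.call(rbind, genes),
                 repeats = do.call(rbind, repeats), spec = spec),
            class = "synthetic_genome")
}

midpoint_sampler_center <- function(bias) {
  a <- 1 + bias
  function(n) stats::rbeta(n, a, a)
}

midpoint_sampler_terminal <- function(bias) {
  b <- 1 + bias
  function(n) {
    left <- stats::runif(n) < 0.5
    ifelse(left, stats::rbeta(n, 1, b), stats::rbeta(n, b, 1))
  }
}

# Draw n non-overlapping intervals on 1..L with midpoints from `sampler`.
# Overlaps are resolved by shifting intervals right, scanning in midpoint
# order; errors out if the packing is infeasible.
place_features <- function(L, n, len_range, sampler) {
  if (n == 0) return(data.frame(start = integer(), end = integer()))
  len <- round(stats::runif(n, len_range[1], len_range[2]))
  if (sum(len) + n > 0.95 * L)
    abort("infeasible packing: %d features of total %d bp on a %d bp chromosome",
          n, sum(len), L)
  mid <- sampler(n) * L
  o <- order(mid)
  len <- len[o]
  start <- pmax(1, pmin(round(mid[o] - len / 2), L - len + 1))
  for (i in seq_len(n)) {
    if (i > 1 && start[i] <= start[i - 1] + len[i - 1])
      start[i] <- start[i - 1] + len[i - 1] + 1
  }
  if (start[n] + len[n] - 1 > L) {
    # ran off the end; pack back leftwards from the last feature
    start[n] <- L - len[n] + 1
    for (i in rev(seq_len(n - 1))) {
      if (start[i] + len[i] >= start[i + 1])
        start[i] <- start[i + 1] - len[i] - 1
    }
    if (start[1] < 1) abort("infeasible packing on %d bp chromosome", L)
  }
  data.frame(start = as.integer(start), end = as.integer(start + len - 1))
}

#' All annotation features of a synthetic genome
#'
#' @param genome a `"synthetic_genome"`.
#' @return a single feature data.frame (genes then repeats, by chromosome).
#' @export
genome_features <- function(genome) {
  f <- rbind(genome$genes, genome$repeats)
  f[order(match(f$seqid, names(genome$lengths)), f$start), , drop = FALSE]
}

#' Write a synthetic genome to FASTA + GFF3
#'
#' @param genome a `"synthetic_genome"` (with sequence).
#' @param fasta,gff3 output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_genome <- function(genome, fasta, gff3) {
  if (is.null(genome$seqs)) abort("genome was generated without sequence")
  write_fasta(data.frame(id = names(genome$seqs), description = "",
                         sequence = unname(genome$seqs),
                         stringsAsFactors = FALSE), fasta)
  write_gff3(genome_features(genome), gff3)
  invisible(list(fasta = fasta, gff3 = gff3))
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d chromosomes, %s bp, %d genes, %d repeats%s\n",
              length(x$lengths), format(sum(x$lengths), big.mark = ","),
              nrow(x$genes), nrow(x$repeats),
              if (is.null(x$seqs)) " (annotation only)" else ""))
  invisible(x)
}
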