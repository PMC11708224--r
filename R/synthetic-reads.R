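#' Specification for a simulated long-read (CLR-like) set
#'
#' Read lengths follow a log-normal law; a fraction of reads are chimeric
#' artifacts formed by concatenating two fragments sampled from loci at
#' least 100 kbp apart (or different chromosomes). The defaults mirror a
#' PacBio CLR run at desk scale: ~20 kbp median length with a right tail,
#' and a 5% chimera rate.
#'
#' @param n_reads number of reads.
#' @param median_length log-normal median read length (bp).
#' @param sigma log-normal sd on the log scale.
#' @param chimera_rate fraction of reads simulated as chimeric, in `[0,1]`.
#' @param min_length floor on simulated read length (bp).
#' @param seed integer seed.
#' @return a list of class `"read_sim_spec"`.
#' @export
read_sim_spec <- function(n_reads = 2000, median_length = 20000,
                          sigma = 0.45, chimera_rate = 0.05,
                          min_length = 2000, seed = 1) {
  stopifnot(is_count(n_reads), chimera_rate >= 0, chimera_rate <= 1,
            median_length > 0, sigma >= 0)
  structure(list(n_reads = n_reads, median_length = median_length,
                 sigma = sigma, chimera_rate = chimera_rate,
                 min_length = min_length, seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Simulate long reads from a genome, planting chimeras
#'
#' Clean reads are contiguous genome substrings; chimeric reads join two
#' fragments from loci >= 100 kbp apart. No base errors or quality values
#' are modelled — the read set exists to exercise overlap-based scrubbing,
#' which only sees lengths and overlap geometry.
#'
#' @param genome a `"synthetic_genome"` with sequence.
#' @param spec a [read_sim_spec()].
#' @return list of class `"read_sim"` with `reads` (data.frame `id`,
#'   `description`, `sequence`), `truth` (data.frame `read`, `length`,
#'   `label` in clean/chimeric, `junction` read position or `NA`), and
#'   `layout` (per-fragment genome placement used by [make_overlaps()]).
#' @export
simulate_long_reads <- function(genome, spec) {
  stopifnot(inherits(genome, "synthetic_genome"), inherits(spec, "read_sim_spec"))
  if (is.null(genome$seqs)) abort("genome was generated without sequence")
  set.seed(spec$seed)
  lens <- genome$lengths
  n <- spec$n_reads
  rlen <- pmax(spec$min_length,
               round(stats::rlnorm(n, log(spec$median_length), spec$sigma)))
  rlen <- pmin(rlen, min(lens) - 1)
  chim <- stats::runif(n) < spec$chimera_rate
  ids <- sprintf("read_%05d", seq_len(n))
  layout <- vector("list", n)
  seqs <- character(n)
  junction <- rep(NA_real_, n)
  pick_locus <- function(flen) {
    chrom <- sample(names(lens), 1, prob = lens)
    start <- sample.int(lens[[chrom]] - flen + 1, 1)
    c(chrom = chrom, start = start)
  }
  for (i in seq_len(n)) {
    if (!chim[i]) {
      loc <- pick_locus(rlen[i])
      gs <- as.numeric(loc["start"])
      layout[[i]] <- data.frame(
        read = ids[i], fragment = 1L, chrom = loc[["chrom"]],
        gstart = gs, gend = gs + rlen[i] - 1,
        rstart = 1, rend = rlen[i], junction_side = "none",
        stringsAsFactors = FALSE)
      seqs[i] <- substr(genome$seqs[[loc[["chrom"]]]], gs, gs + rlen[i] - 1)
    } else {
      l1 <- round(rlen[i] * stats::runif(1, 0.3, 0.7))
      l1 <- min(max(l1, 1000), rlen[i] - 1000)
      l2 <- rlen[i] - l1
      repeat {
        a <- pick_locus(l1)
        b <- pick_locus(l2)
        if (a[["chrom"]] != b[["chrom"]] ||
            abs(as.numeric(a[["start"]]) - as.numeric(b[["start"]])) >= 1e5)
          break
      }
      ga <- as.numeric(a[["start"]]); gb <- as.numeric(b[["start"]])
      layout[[i]] <- data.frame(
        read = ids[i], fragment = c(1L, 2L),
        chrom = c(a[["chrom"]], b[["chrom"]]),
        gstart = c(ga, gb), gend = c(ga + l1 - 1, gb + l2 - 1),
        rstart = c(1, l1 + 1), rend = c(l1, rlen[i]),
        junction_side = c("right", "left"),
        stringsAsFactors = FALSE)
      seqs[i] <- paste0(substr(genome$seqs[[a[["chrom"]]]], ga, ga + l1 - 1),
                        substr(genome$seqs[[b[["chrom"]]]], gb, gb + l2 - 1))
      junction[i] <- l1
    }
  }
  structure(list(
    reads = data.frame(id = ids, description = "", sequence = seqs,
                       stringsAsFactors = FALSE),
    truth = data.frame(read = ids, length = rlen,
                       label = ifelse(chim, "chimeric", "clean"),
                       junction = junction, stringsAsFactors = FALSE),
    layout = do.call(rbind, c(layout, list(make.row.names = FALSE)))),
    class = "read_sim")
}

#' Idealized all-vs-all overlaps for a simulated read set
#'
#' Emits one overlap per pair of read fragments whose true genomic
#' placements intersect by at least `min_overlap` bp. Overlaps never span
#' a chimeric junction: aligned spans are trimmed `junction_margin` bp away
#' from the junction side of a chimeric fragment (an aligner cannot extend
#' an overlap across the artefactual join), so coverage collapses to zero
#' in a window around each planted junction.
#'
#' Each aligned span is additionally shortened by a random 0 to
#' `end_ragged` bp at both ends, emulating the ragged alignment termini of
#' noisy long reads; without this raggedness every true containment is an
#' exact internal match and would be removed by [filter_overlaps()],
#' starving the interior of long reads of coverage in a way real
#' alignments do not.
#'
#' @param sim a `"read_sim"` from [simulate_long_reads()].
#' @param min_overlap minimum emitted overlap length (bp).
#' @param junction_margin bp trimmed at chimeric junctions.
#' @param end_ragged maximum bp of random shortening per alignment end.
#' @param seed seed for the raggedness draws.
#' @return an overlap data.frame in the layout of [read_overlaps_table()].
#' @export
make_overlaps <- function(sim, min_overlap = 2000, junction_margin = 150,
                          end_ragged = 300, seed = 1) {
  stopifnot(inherits(sim, "read_sim"))
  set.seed(seed)
  lay <- sim$layout
  rl <- stats::setNames(sim$truth$length, sim$truth$read)
  res <- list()
  for (chrom in unique(lay$chrom)) {
    fr <- lay[lay$chrom == chrom, , drop = FALSE]
    fr <- fr[order(fr$gstart), , drop = FALSE]
    nf <- nrow(fr)
    if (nf < 2) next
    # fragments j > i with gstart[j] <= gend[i] overlap fragment i
    upper <- findInterval(fr$gend, fr$gstart)
    counts <- pmax(0L, upper - seq_len(nf))
    is <- rep.int(seq_len(nf), counts)
    js <- is + sequence(counts)
    keep <- fr$read[is] != fr$read[js]
    is <- is[keep]; js <- js[keep]
    if (length(is) == 0) next
    # aligned span = genomic intersection, trimmed clear of any chimeric
    # junction on either fragment
    gs_i <- fr$gstart[is] + (fr$junction_side[is] == "left") * junction_margin
    ge_i <- fr$gend[is] - (fr$junction_side[is] == "right") * junction_margin
    gs_j <- fr$gstart[js] + (fr$junction_side[js] == "left") * junction_margin
    ge_j <- fr$gend[js] - (fr$junction_side[js] == "right") * junction_margin
    s2 <- pmax(gs_i, gs_j) + floor(stats::runif(length(is), 0, end_ragged + 1))
    e2 <- pmin(ge_i, ge_j) - floor(stats::runif(length(is), 0, end_ragged + 1))
    ok <- e2 - s2 + 1 >= min_overlap
    if (!any(ok)) next
    is <- is[ok]; js <- js[ok]; s2 <- s2[ok]; e2 <- e2[ok]
    res[[length(res) + 1]] <- data.frame(
      qname = fr$read[is], qlen = unname(rl[fr$read[is]]),
      qstart = fr$rstart[is] + (s2 - fr$gstart[is]),
      qend = fr$rstart[is] + (e2 - fr$gstart[is]),
      strand = "+",
      tname = fr$read[js], tlen = unname(rl[fr$read[js]]),
      tstart = fr$rstart[js] + (s2 - fr$gstart[js]),
      tend = fr$rstart[js] + (e2 - fr$gstart[js]),
      nmatch = e2 - s2 + 1, alen = e2 - s2 + 1, mapq = 60,
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(empty_overlaps())
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Export contigs and a scaffolding order as a 3d-DNA ".assembly" file
#'
#' @param contigs named numeric vector of contig lengths, or a data.frame
#'   with `id` and `sequence` columns.
#' @param order list of character vectors; each vector is one scaffold,
#'   entries are contig names optionally prefixed with `-` for reverse
#'   orientation.
#' @param path output path.
#' @return the `"assembly_map"` written, invisibly.
#' @export
export_assembly_map <- function(contigs, order, path) {
  if (is.data.frame(contigs)) {
    lens <- stats::setNames(nchar(contigs$sequence), contigs$id)
  } else lens <- contigs
  entries <- data.frame(name = names(lens), id = seq_along(lens),
                        length = as.numeric(lens), stringsAsFactors = FALSE)
  idx <- stats::setNames(entries$id, entries$name)
  scaffolds <- lapply(order, function(sc) {
    nm <- sub("^-", "", sc)
    unknown <- setdiff(nm, names(idx))
    if (length(unknown) > 0) abort("unknown contig %s in scaffold order", unknown[1])
    unname(idx[nm] * ifelse(grepl("^-", sc), -1L, 1L))
  })
  map <- structure(list(entries = entries, scaffolds = scaffolds),
                   class = "assembly_map")
  write_assembly_map(map, path)
  invisible(map)
}
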