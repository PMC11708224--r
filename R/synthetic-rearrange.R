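#' Plan of chromosome rearrangements to plant in a synthetic genome
#'
#' Models the rearrangement classes observed between notothenioid genomes:
#' whole-chromosome fusions (as in the chromosome 8 + 11 fusion), interior
#' inversions, and swaps of chromosome ends (terminal translocations).
#'
#' @param fusions data.frame with columns `chrom_a`, `chrom_b` and
#'   optionally `name` (fused chromosome name; defaults to `chrom_a`,
#'   mirroring the convention that the fusion keeps the lower-numbered
#'   label).
#' @param inversions data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive interval to reverse-complement).
#' @param terminal_translocations data.frame with columns `chrom_x`,
#'   `end_x`, `chrom_y`, `end_y` (`"start"` or `"end"`) and `swap_length`
#'   (bp exchanged from each chromosome).
#' @return a list of class `"rearrangement_plan"`.
#' @export
rearrangement_plan <- function(fusions = NULL, inversions = NULL,
                               terminal_translocations = NULL) {
  structure(list(fusions = fusions, inversions = inversions,
                 terminal_translocations = terminal_translocations),
            class = "rearrangement_plan")
}

#' Apply a rearrangement plan to a synthetic genome
#'
#' Produces the rearranged genome plus a truth log of every planted event.
#' Gene ids are preserved, so the two genomes form an orthologous pair for
#' the synteny module. Total non-gap sequence length and gene count are
#' conserved. Edits must not overlap on any chromosome, and inversion /
#' translocation boundaries must not split a feature.
#'
#' @param genome a `"synthetic_genome"` (sequence optional; coordinates and
#'   lengths are always rearranged).
#' @param plan a [rearrangement_plan()].
#' @param fusion_gap bp of `N` inserted at a fusion junction (default 500,
#'   matching the package's scaffolding gap convention).
#' @return list with `genome` (the rearranged `"synthetic_genome"`) and
#'   `truth` (data.frame logging each event with coordinates).
#' @export
apply_rearrangement_plan <- function(genome, plan, fusion_gap = 500) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(plan, "rearrangement_plan"))
  validate_plan(genome, plan)
  g <- genome
  truth <- list()

  if (!is.null(plan$inversions)) {
    for (i in seq_len(nrow(plan$inversions))) {
      ev <- plan$inversions[i, ]
      g <- invert_segment(g, ev$chrom, ev$start, ev$end)
      truth[[length(truth) + 1]] <- data.frame(
        kind = "inversion", chrom1 = ev$chrom, chrom2 = NA_character_,
        start = ev$start, end = ev$end, new_name = NA_character_,
        n_genes = sum(g$genes$seqid == ev$chrom &
                        g$genes$start >= ev$start & g$genes$end <= ev$end),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(plan$terminal_translocations)) {
    for (i in seq_len(nrow(plan$terminal_translocations))) {
      ev <- plan$terminal_translocations[i, ]
      g <- swap_ends(g, ev$chrom_x, ev$end_x, ev$chrom_y, ev$end_y,
                     ev$swap_length)
      truth[[length(truth) + 1]] <- data.frame(
        kind = "translocation", chrom1 = ev$chrom_x, chrom2 = ev$chrom_y,
        start = ev$swap_length, end = ev$swap_length,
        new_name = paste(ev$end_x, ev$end_y, sep = "/"),
        n_genes = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(plan$fusions)) {
    for (i in seq_len(nrow(plan$fusions))) {
      ev <- plan$fusions[i, ]
      nm <- if ("name" %in% names(ev) && !is.na(ev$name)) ev$name else ev$chrom_a
      g <- fuse_chromosomes(g, ev$chrom_a, ev$chrom_b, nm, fusion_gap)
      truth[[length(truth) + 1]] <- data.frame(
        kind = "fusion", chrom1 = ev$chrom_a, chrom2 = ev$chrom_b,
        start = NA_real_, end = NA_real_, new_name = nm,
        n_genes = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  list(genome = g, truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

validate_plan <- function(genome, plan) {
  lens <- genome$lengths
  touched <- list()
  touch <- function(chrom, s, e) {
    if (!chrom %in% names(lens)) abort("unknown chromosome %s in plan", chrom)
    if (s < 1 || e > lens[[chrom]] || s > e)
      abort("edit interval %d-%d outside bounds of %s", s, e, chrom)
    prev <- touched[[chrom]]
    if (!is.null(prev) && any(s <= prev[, 2] & e >= prev[, 1]))
      abort("overlapping edits on chromosome %s", chrom)
    touched[[chrom]] <<- rbind(prev, c(s, e))
  }
  if (!is.null(plan$inversions)) {
    for (i in seq_len(nrow(plan$inversions)))
      with(plan$inversions[i, ], touch(chrom, start, end))
  }
  if (!is.null(plan$terminal_translocations)) {
    for (i in seq_len(nrow(plan$terminal_translocations))) {
      ev <- plan$terminal_translocations[i, ]
      for (side in c("x", "y")) {
        chrom <- ev[[paste0("chrom_", side)]]
        L <- lens[[chrom]]
        if (is.null(L)) abort("unknown chromosome %s in plan", chrom)
        s <- if (ev[[paste0("end_", side)]] == "start") 1 else L - ev$swap_length + 1
        touch(chrom, s, s + ev$swap_length - 1)
      }
    }
  }
  if (!is.null(plan$fusions)) {
    for (i in seq_len(nrow(plan$fusions))) {
      ev <- plan$fusions[i, ]
      touch(ev$chrom_a, 1, lens[[ev$chrom_a]])
      touch(ev$chrom_b, 1, lens[[ev$chrom_b]])
    }
  }
  invisible(TRUE)
}

shift_features <- function(f, chrom, delta, new_chrom = chrom,
                           from = 1, to = Inf) {
  sel <- f$seqid == chrom & f$start >= from & f$end <= to
  f$start[sel] <- f$start[sel] + delta
  f$end[sel] <- f$end[sel] + delta
  f$seqid[sel] <- new_chrom
  f
}

check_no_boundary_features <- function(f, chrom, s, e) {
  cut <- f$seqid == chrom &
    ((f$start < s & f$end >= s) | (f$start <= e & f$end > e))
  if (any(cut))
    abort("edit boundary %d-%d on %s splits feature %s", s, e, chrom,
          gff_attr(f[cut, , drop = FALSE], "ID")[1])
  invisible(TRUE)
}

invert_segment <- function(g, chrom, s, e) {
  for (tab in c("genes", "repeats")) check_no_boundary_features(g[[tab]], chrom, s, e)
  if (!is.null(g$seqs)) {
    seq <- g$seqs[[chrom]]
    g$seqs[[chrom]] <- paste0(substr(seq, 1, s - 1),
                              revcomp(substr(seq, s, e)),
                              substr(seq, e + 1, nchar(seq)))
  }
  flip <- function(f) {
    sel <- f$seqid == chrom & f$start >= s & f$end <= e
    ns <- s + (e - f$end[sel])
    ne <- s + (e - f$start[sel])
    f$start[sel] <- ns
    f$end[sel] <- ne
    f$strand[sel] <- chartr("+-", "-+", f$strand[sel])
    f
  }
  g$genes <- flip(g$genes)
  g$repeats <- flip(g$repeats)
  g
}

swap_ends <- function(g, chrom_x, end_x, chrom_y, end_y, s) {
  lx <- g$lengths[[chrom_x]]
  ly <- g$lengths[[chrom_y]]
  seg <- function(chrom, end, L) {
    if (end == "start") c(1, s) else c(L - s + 1, L)
  }
  ix <- seg(chrom_x, end_x, lx)
  iy <- seg(chrom_y, end_y, ly)
  for (tab in c("genes", "repeats")) {
    check_no_boundary_features(g[[tab]], chrom_x, ix[1], ix[2])
    check_no_boundary_features(g[[tab]], chrom_y, iy[1], iy[2])
  }
  if (!is.null(g$seqs)) {
    sx <- g$seqs[[chrom_x]]; sy <- g$seqs[[chrom_y]]
    px <- substr(sx, ix[1], ix[2]); py <- substr(sy, iy[1], iy[2])
    repl <- function(seq, iv, piece) {
      paste0(substr(seq, 1, iv[1] - 1), piece, substr(seq, iv[2] + 1, nchar(seq)))
    }
    g$seqs[[chrom_x]] <- repl(sx, ix, py)
    g$seqs[[chrom_y]] <- repl(sy, iy, px)
  }
  # move features of each segment to the other chromosome, same end
  move <- function(f) {
    selx <- f$seqid == chrom_x & f$start >= ix[1] & f$end <= ix[2]
    sely <- f$seqid == chrom_y & f$start >= iy[1] & f$end <= iy[2]
    dx2y <- iy[1] - ix[1]   # segment origins align (equal swap lengths)
    f$start[selx] <- f$start[selx] + dx2y
    f$end[selx] <- f$end[selx] + dx2y
    f$seqid[selx] <- chrom_y
    f$start[sely] <- f$start[sely] - dx2y
    f$end[sely] <- f$end[sely] - dx2y
    f$seqid[sely] <- chrom_x
    f
  }
  g$genes <- move(g$genes)
  g$repeats <- move(g$repeats)
  g
}

fuse_chromosomes <- function(g, chrom_a, chrom_b, name, gap) {
  la <- g$lengths[[chrom_a]]
  lb <- g$lengths[[chrom_b]]
  off <- la + gap
  if (!is.null(g$seqs)) {
    fused <- paste0(g$seqs[[chrom_a]], strrep("N", gap), g$seqs[[chrom_b]])
    g$seqs <- g$seqs[setdiff(names(g$seqs), c(chrom_a, chrom_b))]
    g$seqs[[name]] <- fused
  }
  keep <- setdiff(names(g$lengths), c(chrom_a, chrom_b))
  lens <- g$lengths[keep]
  lens[[name]] <- la + gap + lb
  g$lengths <- lens
  refit <- function(f) {
    f <- shift_features(f, chrom_b, off, new_chrom = name)
    f$seqid[f$seqid == chrom_a] <- name
    f
  }
  g$genes <- refit(g$genes)
  g$repeats <- refit(g$repeats)
  g
}

# ---- planting helpers -------------------------------------------------------

# Smallest boundary position move that leaves no feature straddling `pos`
# (the first position of a terminal "end" segment, or the last of a "start"
# segment); features are genes + repeats.
clear_cut <- function(genome, chrom, pos, direction) {
  f <- rbind(genome$genes[genome$genes$seqid == chrom, c("start", "end")],
             genome$repeats[genome$repeats$seqid == chrom, c("start", "end")])
  repeat {
    hit <- f$start < pos & f$end >= pos
    if (!any(hit)) return(pos)
    pos <- if (direction < 0) min(f$start[hit]) - 1 else max(f$end[hit]) + 1
  }
}

#' Choose a terminal-swap length capturing a given number of genes
#'
#' Picks the smallest swap length such that the designated end of *both*
#' chromosomes contains at least `n_genes` genes, then nudges the cut so no
#' gene or repeat is split on either chromosome.
#'
#' @param genome a `"synthetic_genome"`.
#' @param chrom_x,chrom_y the chromosomes to swap ends between.
#' @param n_genes minimum genes captured from each chromosome.
#' @param end `"start"` or `"end"` (same end on both chromosomes).
#' @return swap length in bp.
#' @export
terminal_swap_length <- function(genome, chrom_x, chrom_y, n_genes,
                                 end = "end") {
  need <- function(chrom) {
    gg <- genome$genes[genome$genes$seqid == chrom, , drop = FALSE]
    gg <- gg[order(gg$start), , drop = FALSE]
    if (nrow(gg) < n_genes) abort("chromosome %s has fewer than %d genes",
                                  chrom, n_genes)
    L <- genome$lengths[[chrom]]
    if (end == "end") L - gg$start[nrow(gg) - n_genes + 1] + 2
    else gg$end[n_genes] + 1
  }
  s <- max(need(chrom_x), need(chrom_y))
  repeat {
    s_new <- s
    for (chrom in c(chrom_x, chrom_y)) {
      L <- genome$lengths[[chrom]]
      if (end == "end") {
        pos <- clear_cut(genome, chrom, L - s_new + 1, direction = -1)
        s_new <- L - pos + 1
      } else {
        pos <- clear_cut(genome, chrom, s_new + 1, direction = 1)
        s_new <- pos - 1
      }
    }
    if (s_new == s) break
    s <- s_new
  }
  Lmin <- min(genome$lengths[[chrom_x]], genome$lengths[[chrom_y]])
  if (s >= Lmin) abort("swap length %d exceeds a chromosome", s)
  s
}

#' Choose an inversion interval spanning a block of consecutive genes
#'
#' Returns the 1-based inclusive interval covering genes
#' `first_gene_idx .. first_gene_idx + n_genes - 1` (in chromosomal order),
#' expanded outward so no gene or repeat straddles either boundary.
#'
#' @param genome a `"synthetic_genome"`.
#' @param chrom chromosome name.
#' @param first_gene_idx index of the first gene of the block.
#' @param n_genes genes in the inverted block.
#' @return numeric vector `c(start, end)`.
#' @export
inversion_interval <- function(genome, chrom, first_gene_idx, n_genes) {
  gg <- genome$genes[genome$genes$seqid == chrom, , drop = FALSE]
  gg <- gg[order(gg$start), , drop = FALSE]
  last <- first_gene_idx + n_genes - 1
  if (first_gene_idx < 1 || last > nrow(gg))
    abort("gene block %d..%d outside chromosome %s (%d genes)",
          first_gene_idx, last, chrom, nrow(gg))
  s <- clear_cut(genome, chrom, gg$start[first_gene_idx] - 1, direction = -1)
  e <- clear_cut(genome, chrom, gg$end[last] + 2, direction = 1) - 1
  c(max(1, s), min(genome$lengths[[chrom]], e))
}
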