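#' Reciprocal best hits between two gene sets
#'
#' A pair (a, b) is kept iff b is a's best hit by bitscore in the A-vs-B
#' table and a is b's best hit in the B-vs-A table. Ties break toward
#' higher percent identity, then the lexicographically smaller subject id,
#' so the result is deterministic. The output is a bijection on its
#' support.
#'
#' @param hits_ab,hits_ba hit data.frames as from [read_hits_table()].
#' @return data.frame with columns `gene_a`, `gene_b`, `bitscore`,
#'   `identity_pct` (taken from the A-vs-B direction).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best_ab <- best_per_query(hits_ab)
  best_ba <- best_per_query(hits_ba)
  back <- stats::setNames(best_ba$subject_gene, best_ba$query_gene)
  keep <- !is.na(back[best_ab$subject_gene]) &
    back[best_ab$subject_gene] == best_ab$query_gene
  out <- best_ab[keep, , drop = FALSE]
  data.frame(gene_a = out$query_gene, gene_b = out$subject_gene,
             bitscore = out$bitscore, identity_pct = out$identity_pct,
             stringsAsFactors = FALSE, row.names = NULL)
}

best_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$query_gene, -hits$bitscore, -hits$identity_pct,
             hits$subject_gene)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_gene), , drop = FALSE]
}

#' Ortholog pairs between two annotated genomes sharing gene ids
#'
#' Builds the positional ortholog table the clustering step consumes,
#' pairing genes by identical `ID` attribute — the idealised equivalent of
#' a reciprocal-best-hit map for genomes descended from a common synthetic
#' ancestor. Gene position is the midpoint of its annotated span.
#'
#' @param genes_a,genes_b gene feature data.frames.
#' @return data.frame with `gene_a`, `gene_b`, `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b`, `bitscore`.
#' @export
ortholog_pairs_from_annotations <- function(genes_a, genes_b) {
  ida <- gff_attr(genes_a, "ID")
  idb <- gff_attr(genes_b, "ID")
  common <- intersect(ida, idb)
  ma <- match(common, ida)
  mb <- match(common, idb)
  data.frame(gene_a = common, gene_b = common,
             chrom_a = genes_a$seqid[ma],
             pos_a = (genes_a$start[ma] + genes_a$end[ma]) / 2,
             chrom_b = genes_b$seqid[mb],
             pos_b = (genes_b$start[mb] + genes_b$end[mb]) / 2,
             bitscore = NA_real_, stringsAsFactors = FALSE)
}

#' Attach genome positions to an RBH pair table
#'
#' @param pairs data.frame from [reciprocal_best_hits()].
#' @param genes_a,genes_b gene feature data.frames whose `ID` attributes
#'   contain the pair gene ids.
#' @return `pairs` with `chrom_a`, `pos_a`, `chrom_b`, `pos_b` columns
#'   added (positions are annotated-span midpoints).
#' @export
attach_positions <- function(pairs, genes_a, genes_b) {
  ida <- gff_attr(genes_a, "ID")
  idb <- gff_attr(genes_b, "ID")
  ma <- match(pairs$gene_a, ida)
  mb <- match(pairs$gene_b, idb)
  if (anyNA(ma)) abort("unknown gene id %s in genome A annotation",
                       pairs$gene_a[is.na(ma)][1])
  if (anyNA(mb)) abort("unknown gene id %s in genome B annotation",
                       pairs$gene_b[is.na(mb)][1])
  pairs$chrom_a <- genes_a$seqid[ma]
  pairs$pos_a <- (genes_a$start[ma] + genes_a$end[ma]) / 2
  pairs$chrom_b <- genes_b$seqid[mb]
  pairs$pos_b <- (genes_b$start[mb] + genes_b$end[mb]) / 2
  pairs
}

#' Clustering parameters for the conserved-synteny engine
#'
#' @param window_size seed size in genes for opening a cluster.
#' @param max_gap maximum intervening non-syntenic genes tolerated between
#'   consecutive cluster members.
#' @param min_cluster_size minimum members for a reported cluster.
#' @param fusion_min_fraction minimum fraction of a chromosome's clustered
#'   genes on a secondary partner before dual orthology (a fusion
#'   candidate) is considered.
#' @param terminal_fraction outer fraction of a chromosome counted as
#'   terminal for translocation calls.
#' @return a list of class `"cluster_params"`.
#' @export
cluster_params <- function(window_size = 5, max_gap = 3,
                           min_cluster_size = 5, fusion_min_fraction = 0.2,
                           terminal_fraction = 0.2) {
  stopifnot(window_size > 0, max_gap >= 0, min_cluster_size > 0,
            fusion_min_fraction > 0, fusion_min_fraction <= 0.5)
  structure(list(window_size = window_size, max_gap = max_gap,
                 min_cluster_size = min_cluster_size,
                 fusion_min_fraction = fusion_min_fraction,
                 terminal_fraction = terminal_fraction),
            class = "cluster_params")
}

#' Build conserved-synteny clusters from positioned ortholog pairs
#'
#' Genes of genome A are walked in chromosomal order. A run of pairs whose
#' partners lie on one B chromosome is chained into a cluster, tolerating
#' up to `max_gap` intervening A genes (paired elsewhere or unpaired)
#' between consecutive members; a break beyond that closes the cluster.
#' Clusters below `min_cluster_size` members are discarded. Cluster
#' orientation is the sign of the Spearman rank correlation between member
#' positions on the two genomes (`|rho| < 0.5` reports "mixed").
#'
#' @param pairs positioned pair table ([attach_positions()] or
#'   [ortholog_pairs_from_annotations()]).
#' @param genes_a full genome-A gene annotation, used to count intervening
#'   genes; `NULL` counts interlopers among paired genes only.
#' @param params a [cluster_params()].
#' @return list of class `"synteny_clusters"`: `clusters` (data.frame
#'   `cluster_id`, `chrom_a`, `chrom_b`, `n`, `start_a`, `end_a`,
#'   `start_b`, `end_b`, `rho`, `orientation`) and `members` (list of pair
#'   data.frames, ordered by `pos_a`).
#' @export
build_synteny_clusters <- function(pairs, genes_a = NULL,
                                   params = cluster_params()) {
  stopifnot(all(c("chrom_a", "pos_a", "chrom_b", "pos_b") %in% names(pairs)))
  if (!is.null(genes_a)) {
    ida <- gff_attr(genes_a, "ID")
    m <- match(pairs$gene_a, ida)
    if (anyNA(m)) abort("unknown gene id %s in genome A annotation",
                        pairs$gene_a[is.na(m)][1])
    ord <- order(genes_a$seqid, genes_a$start)
    rank_of <- match(seq_len(nrow(genes_a)), ord)
    pairs$rank_a <- rank_of[m]
  }
  clusters <- list()
  members <- list()
  for (chrom in unique(pairs$chrom_a)) {
    p <- pairs[pairs$chrom_a == chrom, , drop = FALSE]
    p <- p[order(p$pos_a), , drop = FALSE]
    if (is.null(genes_a)) p$rank_a <- seq_len(nrow(p))
    open <- list()   # chrom_b -> list(idx, last_rank)
    for (i in seq_len(nrow(p))) {
      b <- p$chrom_b[i]
      cur <- open[[b]]
      if (!is.null(cur) && p$rank_a[i] - cur$last_rank - 1 <= params$max_gap) {
        cur$idx <- c(cur$idx, i)
        cur$last_rank <- p$rank_a[i]
        open[[b]] <- cur
      } else {
        if (!is.null(cur)) {
          clusters[[length(clusters) + 1]] <- list(chrom = chrom, b = b,
                                                   idx = cur$idx, p = p)
        }
        open[[b]] <- list(idx = i, last_rank = p$rank_a[i])
      }
    }
    for (b in names(open)) {
      clusters[[length(clusters) + 1]] <- list(chrom = chrom, b = b,
                                               idx = open[[b]]$idx, p = p)
    }
  }
  keep <- Filter(function(cl) length(cl$idx) >= params$min_cluster_size,
                 clusters)
  rows <- lapply(seq_along(keep), function(k) {
    cl <- keep[[k]]
    mem <- cl$p[cl$idx, , drop = FALSE]
    rho <- if (nrow(mem) >= 2)
      suppressWarnings(stats::cor(mem$pos_a, mem$pos_b, method = "spearman"))
    else 1
    if (is.na(rho)) rho <- 0
    orientation <- if (rho >= 0.5) 1L else if (rho <= -0.5) -1L else 0L
    members[[k]] <<- mem
    data.frame(cluster_id = k, chrom_a = cl$chrom, chrom_b = cl$b,
               n = nrow(mem), start_a = min(mem$pos_a), end_a = max(mem$pos_a),
               start_b = min(mem$pos_b), end_b = max(mem$pos_b),
               rho = rho, orientation = orientation, stringsAsFactors = FALSE)
  })
  structure(list(
    clusters = if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
               else empty_cluster_df(),
    members = members, params = params), class = "synteny_clusters")
}

empty_cluster_df <- function() {
  data.frame(cluster_id = integer(), chrom_a = character(),
             chrom_b = character(), n = integer(), start_a = numeric(),
             end_a = numeric(), start_b = numeric(), end_b = numeric(),
             rho = numeric(), orientation = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.synteny_clusters <- function(x, ...) {
  cat(sprintf("synteny clusters: %d cluster(s) over %d chromosome pair(s), %d gene pair(s)\n",
              nrow(x$clusters),
              nrow(unique(x$clusters[, c("chrom_a", "chrom_b")])),
              sum(x$clusters$n)))
  invisible(x)
}

#' Assign chromosome orthology from synteny clusters
#'
#' Each A chromosome is assigned the B chromosome holding the plurality of
#' its clustered genes. When a second B chromosome holds at least
#' `fusion_min_fraction` of the clustered genes *and* its clusters occupy
#' an A interval disjoint from the primary partner's, dual orthology is
#' reported — the signature of a chromosome fusion.
#'
#' @param clusters a `"synteny_clusters"` object.
#' @param chroms_a optional full list of A chromosomes, so chromosomes with
#'   no clustered genes appear as "unassigned".
#' @return data.frame with `chrom_a`, `ortholog`, `secondary`, `status`
#'   (assigned / dual / unassigned).
#' @export
assign_chromosome_orthology <- function(clusters, chroms_a = NULL) {
  cl <- clusters$clusters
  frac <- clusters$params$fusion_min_fraction
  chroms <- if (is.null(chroms_a)) unique(cl$chrom_a) else chroms_a
  rows <- lapply(chroms, function(chrom) {
    cc <- cl[cl$chrom_a == chrom, , drop = FALSE]
    if (nrow(cc) == 0) {
      return(data.frame(chrom_a = chrom, ortholog = NA_character_,
                        secondary = NA_character_, status = "unassigned",
                        stringsAsFactors = FALSE))
    }
    cnt <- tapply(cc$n, cc$chrom_b, sum)
    cnt <- sort(cnt, decreasing = TRUE)
    primary <- names(cnt)[1]
    secondary <- NA_character_
    status <- "assigned"
    if (length(cnt) > 1 && cnt[2] / sum(cnt) >= frac) {
      cand <- names(cnt)[2]
      iv1 <- range(c(cc$start_a[cc$chrom_b == primary],
                     cc$end_a[cc$chrom_b == primary]))
      iv2 <- range(c(cc$start_a[cc$chrom_b == cand],
                     cc$end_a[cc$chrom_b == cand]))
      if (iv1[2] < iv2[1] || iv2[2] < iv1[1]) {
        secondary <- cand
        status <- "dual"
      }
    }
    data.frame(chrom_a = chrom, ortholog = primary, secondary = secondary,
               status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Detect fusions, inversions and terminal translocations
#'
#' Three signatures are called from the clustered ortholog map:
#' \describe{
#'   \item{fusion}{an A chromosome with dual orthology — two B partners
#'     occupying disjoint intervals (see
#'     [assign_chromosome_orthology()]).}
#'   \item{inversion}{within a cluster, a maximal interior run of members
#'     whose local order opposes the cluster's dominant orientation,
#'     flanked on both sides by dominant-orientation runs, with at least
#'     `min_cluster_size` members.}
#'   \item{translocation}{a cluster touching the outer
#'     `terminal_fraction` of its A chromosome whose B partner differs
#'     from the chromosome's assigned ortholog. Reciprocal terminal calls
#'     (each side's partner being the other's ortholog) are paired into a
#'     single end-swap call.}
#' }
#'
#' @param clusters a `"synteny_clusters"` object.
#' @param naming orthology table from [assign_chromosome_orthology()].
#' @param chrom_lengths_a named lengths of the A chromosomes (bp), used to
#'   delimit terminal regions.
#' @return data.frame of calls: `kind`, `chrom_a`, `chrom_b`, `chrom_b2`,
#'   `start_a`, `end_a`, `support`, `note`.
#' @export
detect_rearrangements <- function(clusters, naming, chrom_lengths_a) {
  params <- clusters$params
  calls <- list()
  add <- function(...) calls[[length(calls) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  # A dual-orthology partner whose clusters stay within the outer part of
  # the chromosome is the signature of a swapped end, not a fusion: a fused
  # sub-chromosome contributes roughly half the object and reaches its
  # interior. Such rows are demoted to single orthology here so their
  # clusters feed the translocation logic below.
  for (i in which(naming$status == "dual")) {
    cc <- clusters$clusters
    sel <- cc$chrom_a == naming$chrom_a[i] & cc$chrom_b == naming$secondary[i]
    iv <- c(min(cc$start_a[sel]), max(cc$end_a[sel]))
    L <- chrom_lengths_a[[naming$chrom_a[i]]]
    margin <- 1.5 * params$terminal_fraction * L
    if (iv[1] >= L - margin || iv[2] <= margin) {
      naming$status[i] <- "assigned"
      naming$secondary[i] <- NA_character_
    }
  }

  dual <- naming[naming$status == "dual", , drop = FALSE]
  for (i in seq_len(nrow(dual))) {
    cc <- clusters$clusters
    sel <- cc$chrom_a == dual$chrom_a[i] &
      cc$chrom_b %in% c(dual$ortholog[i], dual$secondary[i])
    add(kind = "fusion", chrom_a = dual$chrom_a[i],
        chrom_b = dual$ortholog[i], chrom_b2 = dual$secondary[i],
        start_a = min(cc$start_a[sel]), end_a = max(cc$end_a[sel]),
        support = sum(cc$n[sel]), note = "dual orthology")
  }

  ortho <- stats::setNames(naming$ortholog, naming$chrom_a)
  for (k in seq_len(nrow(clusters$clusters))) {
    cl <- clusters$clusters[k, ]
    mem <- clusters$members[[k]]
    if (nrow(mem) < params$min_cluster_size + 2) next
    steps <- sign(diff(mem$pos_b))
    dominant <- sign(sum(steps))
    if (dominant == 0) next
    r <- rle(as.integer(steps))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$lengths)) {
      if (r$values[j] != -dominant) next
      if (j == 1 || j == length(r$lengths)) next
      if (r$values[j - 1] != dominant || r$values[j + 1] != dominant) next
      n_members <- r$lengths[j] + 1
      if (n_members < params$min_cluster_size) next
      mi <- starts[j]:(ends[j] + 1)   # steps j..k involve members j..k+1
      add(kind = "inversion", chrom_a = cl$chrom_a, chrom_b = cl$chrom_b,
          chrom_b2 = NA_character_, start_a = min(mem$pos_a[mi]),
          end_a = max(mem$pos_a[mi]), support = n_members,
          note = "orientation reversal")
    }
  }

  cand <- list()
  cc <- clusters$clusters
  for (k in seq_len(nrow(cc))) {
    cl <- cc[k, ]
    own <- ortho[[cl$chrom_a]]
    if (is.null(own) || is.na(own) || cl$chrom_b == own) next
    sec <- naming$secondary[naming$chrom_a == cl$chrom_a]
    if (length(sec) == 1 && !is.na(sec) && cl$chrom_b == sec) next
    L <- chrom_lengths_a[[cl$chrom_a]]
    if (is.null(L)) abort("no length given for chromosome %s", cl$chrom_a)
    at_start <- cl$start_a <= params$terminal_fraction * L
    at_end <- cl$end_a >= (1 - params$terminal_fraction) * L
    if (!at_start && !at_end) next
    cand[[length(cand) + 1]] <- data.frame(
      chrom_a = cl$chrom_a, chrom_b = cl$chrom_b,
      end = if (at_start) "start" else "end", start_a = cl$start_a,
      end_a = cl$end_a, support = cl$n, stringsAsFactors = FALSE)
  }
  used <- rep(FALSE, length(cand))
  for (i in seq_along(cand)) {
    if (used[i]) next
    ci <- cand[[i]]
    partner_a <- names(ortho)[!is.na(ortho) & ortho == ci$chrom_b]
    paired <- FALSE
    for (j in seq_along(cand)) {
      if (j == i || used[j]) next
      cj <- cand[[j]]
      if (cj$chrom_a %in% partner_a && !is.na(ortho[[ci$chrom_a]]) &&
          cj$chrom_b == ortho[[ci$chrom_a]]) {
        add(kind = "translocation", chrom_a = ci$chrom_a,
            chrom_b = cj$chrom_a, chrom_b2 = NA_character_,
            start_a = ci$start_a, end_a = ci$end_a,
            support = ci$support + cj$support,
            note = sprintf("end swap (%s/%s)", ci$end, cj$end))
        used[c(i, j)] <- TRUE
        paired <- TRUE
        break
      }
    }
    if (!paired) {
      add(kind = "translocation", chrom_a = ci$chrom_a, chrom_b = ci$chrom_b,
          chrom_b2 = NA_character_, start_a = ci$start_a, end_a = ci$end_a,
          support = ci$support, note = sprintf("terminal (%s)", ci$end))
      used[i] <- TRUE
    }
  }
  if (length(calls) == 0) {
    return(data.frame(kind = character(), chrom_a = character(),
                      chrom_b = character(), chrom_b2 = character(),
                      start_a = numeric(), end_a = numeric(),
                      support = integer(), note = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(calls, list(make.row.names = FALSE)))
}
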