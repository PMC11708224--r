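#' Construct a multiple sequence alignment object
#'
#' @param names taxon names (unique).
#' @param rows aligned sequences (equal length, DNA plus `-` gaps).
#' @return a list of class `"msa"` with `names` and `rows`.
#' @export
new_msa <- function(names, rows) {
  if (length(names) != length(rows)) abort("names and rows differ in length")
  if (anyDuplicated(names)) abort("duplicate taxon %s in alignment",
                                  names[duplicated(names)][1])
  if (length(rows) > 0 && length(unique(nchar(rows))) != 1)
    abort("alignment rows are not all the same length")
  structure(list(names = as.character(names), rows = as.character(rows)),
            class = "msa")
}

#' Read an MSA from aligned FASTA
#'
#' @param path path to an aligned FASTA file.
#' @return an `"msa"` object.
#' @export
read_msa <- function(path) {
  rec <- read_fasta(path)
  new_msa(rec$id, rec$sequence)
}

#' Write an MSA to aligned FASTA
#'
#' @param msa an `"msa"` object.
#' @param path output path.
#' @param line_width sequence characters per line.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, line_width = 60) {
  write_fasta(data.frame(id = msa$names, description = "",
                         sequence = msa$rows, stringsAsFactors = FALSE),
              path, line_width = line_width)
}

msa_matrix <- function(msa) {
  if (length(msa$rows) == 0 || nchar(msa$rows[1]) == 0)
    return(matrix(character(), nrow = length(msa$rows), ncol = 0))
  do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
}

#' Remove alignment columns with a high gap fraction
#'
#' Columns whose gap (`-`) fraction exceeds `max_gap_rate` are dropped;
#' row order is preserved. Mirrors entropy-free gap filtering as used
#' before supermatrix construction.
#'
#' @param msa an `"msa"` object.
#' @param max_gap_rate maximum tolerated per-column gap fraction
#'   (default 0.2).
#' @return the filtered `"msa"`; warns if no columns survive.
#' @export
filter_gappy_columns <- function(msa, max_gap_rate = 0.2) {
  stopifnot(inherits(msa, "msa"))
  m <- msa_matrix(msa)
  if (ncol(m) == 0) return(msa)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_rate
  if (!any(keep)) {
    warnf("all %d columns exceeded gap rate %.2f; empty alignment returned",
          ncol(m), max_gap_rate)
    return(new_msa(msa$names, rep("", length(msa$names))))
  }
  new_msa(msa$names,
          apply(m[, keep, drop = FALSE], 1, paste, collapse = ""))
}

#' Concatenate alignments into a supermatrix with a partition table
#'
#' Taxa are the union across alignments (ordered by first appearance); a
#' taxon missing from one alignment is padded with an all-gap row for that
#' block. The partition table gives 1-based inclusive column ranges per
#' source alignment, in input order.
#'
#' @param msas named list of `"msa"` objects.
#' @return list with `supermatrix` (an `"msa"`) and `partitions`
#'   (data.frame `name`, `start`, `end`).
#' @export
concat_and_partition <- function(msas) {
  stopifnot(length(msas) > 0, !is.null(names(msas)))
  for (m in msas) stopifnot(inherits(m, "msa"))
  taxa <- unique(unlist(lapply(msas, `[[`, "names")))
  widths <- vapply(msas, function(m)
    if (length(m$rows)) nchar(m$rows[1]) else 0L, numeric(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1
  blocks <- lapply(msas, function(m) {
    w <- if (length(m$rows)) nchar(m$rows[1]) else 0L
    idx <- match(taxa, m$names)
    out <- ifelse(is.na(idx), strrep("-", w), m$rows[idx])
    out
  })
  rows <- do.call(paste0, blocks)
  list(supermatrix = new_msa(taxa, rows),
       partitions = data.frame(name = names(msas), start = starts,
                               end = ends, row.names = NULL,
                               stringsAsFactors = FALSE))
}

#' Remap gene identifiers through a two-column mapping table
#'
#' Ids present in the map are replaced; absent ids are kept and reported.
#' A requested id mapping to more than one target is an error.
#'
#' @param ids character vector of gene ids.
#' @param map data.frame whose first two columns are (from, to).
#' @return list with `ids` (remapped vector) and `unmapped` (ids not in
#'   the map).
#' @export
remap_gene_ids <- function(ids, map) {
  from <- as.character(map[[1]])
  to <- as.character(map[[2]])
  dup <- unique(from[duplicated(from)])
  for (d in intersect(dup, ids)) {
    if (length(unique(to[from == d])) > 1)
      abort("id %s has conflicting mappings", d)
  }
  m <- match(ids, from)
  out <- ifelse(is.na(m), ids, to[m])
  list(ids = out, unmapped = unique(ids[is.na(m)]))
}
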