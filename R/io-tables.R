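#' Read a 3d-DNA ".assembly" scaffolding map
#'
#' The dialect emitted by the 3d-DNA Hi-C scaffolding pipeline: header
#' lines `>name id length` declaring contigs (both the plain and the
#' post-review `>name fragment ...` name forms are accepted verbatim),
#' followed by whitespace-separated signed-id lines, one scaffold per line;
#' a negative id means reverse orientation.
#'
#' @param path path to a `.assembly` file.
#' @return a list of class `"assembly_map"` with `entries` (data.frame
#'   `name`, `id`, `length`) and `scaffolds` (list of signed integer
#'   vectors).
#' @export
read_assembly_map <- function(path) {
  if (!file.exists(path)) abort(".assembly file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  ent <- strsplit(sub("^>", "", lines[hdr]), "\\s+")
  if (any(lengths(ent) < 3)) abort("malformed header line in .assembly file")
  entries <- data.frame(
    name = vapply(ent, `[`, character(1), 1),
    id = as.integer(vapply(ent, function(x) x[length(x) - 1], character(1))),
    length = as.numeric(vapply(ent, function(x) x[length(x)], character(1))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(entries$id))
    abort("duplicate internal id %d in .assembly header",
          entries$id[duplicated(entries$id)][1])
  scaffolds <- lapply(strsplit(trimws(lines[!hdr]), "\\s+"), as.integer)
  used <- as.integer(unlist(scaffolds))
  undeclared <- setdiff(abs(used), entries$id)
  if (length(undeclared) > 0)
    abort("scaffold line references undeclared id %d", undeclared[1])
  if (anyDuplicated(abs(used)))
    abort("id %d used in more than one scaffold position",
          abs(used)[duplicated(abs(used))][1])
  structure(list(entries = entries, scaffolds = scaffolds),
            class = "assembly_map")
}

#' Write a 3d-DNA ".assembly" scaffolding map
#'
#' @param map an `"assembly_map"` (see [read_assembly_map()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assembly_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(">%s %d %s", map$entries$name, map$entries$id,
                     format_bp(map$entries$length)), con)
  for (sc in map$scaffolds)
    writeLines(paste(sc, collapse = " "), con)
  invisible(path)
}

#' Read a BLAST-tab-like ortholog hit table
#'
#' Four tab-separated columns: query gene, subject gene, bitscore,
#' percent identity.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `query_gene`, `subject_gene`,
#'   `bitscore`, `identity_pct`.
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) abort("hits table not found: %s", path)
  lines <- readLines(path)
  lines2 <- lines[nzchar(trimws(lines))]
  if (length(lines2) == 0) {
    return(data.frame(query_gene = character(), subject_gene = character(),
                      bitscore = numeric(), identity_pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines2, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad) > 0)
    abort("line %d: expected 4 columns, found %d",
          which(nzchar(trimws(lines)))[bad[1]], lengths(parts)[bad[1]])
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  out <- data.frame(query_gene = m[, 1], subject_gene = m[, 2],
                    bitscore = as.numeric(m[, 3]),
                    identity_pct = as.numeric(m[, 4]),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$query_gene)) || any(!nzchar(out$subject_gene)))
    abort("empty gene id in hits table")
  if (any(is.na(out$bitscore)) || any(is.na(out$identity_pct)))
    abort("non-numeric bitscore/identity in hits table")
  out
}

#' Read a PAF-like all-vs-all overlap table
#'
#' The 12 standard PAF columns. PAF coordinates are 0-based half-open;
#' they are converted on read to the package-wide 1-based inclusive
#' convention (`start+1`, `end` unchanged).
#'
#' @param path path to the TSV.
#' @return data.frame with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`.
#' @export
read_overlaps_table <- function(path) {
  if (!file.exists(path)) abort("overlap table not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_overlaps())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12)
  if (length(bad) > 0)
    abort("line %d: expected 12 columns, found %d", bad[1],
          lengths(parts)[bad[1]])
  m <- t(vapply(parts, function(p) p[1:12], character(12)))
  out <- data.frame(
    qname = m[, 1], qlen = as.numeric(m[, 2]),
    qstart = as.numeric(m[, 3]) + 1, qend = as.numeric(m[, 4]),
    strand = m[, 5],
    tname = m[, 6], tlen = as.numeric(m[, 7]),
    tstart = as.numeric(m[, 8]) + 1, tend = as.numeric(m[, 9]),
    nmatch = as.numeric(m[, 10]), alen = as.numeric(m[, 11]),
    mapq = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  validate_overlaps(out)
  out
}

empty_overlaps <- function() {
  data.frame(qname = character(), qlen = numeric(), qstart = numeric(),
             qend = numeric(), strand = character(), tname = character(),
             tlen = numeric(), tstart = numeric(), tend = numeric(),
             nmatch = numeric(), alen = numeric(), mapq = numeric(),
             stringsAsFactors = FALSE)
}

validate_overlaps <- function(ov) {
  if (nrow(ov) == 0) return(invisible(TRUE))
  ok <- ov$qstart >= 1 & ov$qstart <= ov$qend & ov$qend <= ov$qlen &
    ov$tstart >= 1 & ov$tstart <= ov$tend & ov$tend <= ov$tlen
  if (!all(ok)) abort("overlap row %d: span outside read bounds", which(!ok)[1])
  invisible(TRUE)
}

#' Write a PAF-like overlap table
#'
#' Inverse of [read_overlaps_table()]: internal 1-based inclusive spans are
#' written back as 0-based half-open PAF columns.
#'
#' @param overlaps overlap data.frame (internal convention).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlaps_table <- function(overlaps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(overlaps) > 0) {
    writeLines(paste(overlaps$qname, format_bp(overlaps$qlen),
                     format_bp(overlaps$qstart - 1), format_bp(overlaps$qend),
                     overlaps$strand, overlaps$tname, format_bp(overlaps$tlen),
                     format_bp(overlaps$tstart - 1), format_bp(overlaps$tend),
                     format_bp(overlaps$nmatch), format_bp(overlaps$alen),
                     format_bp(overlaps$mapq), sep = "\t"), con)
  }
  invisible(path)
}
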