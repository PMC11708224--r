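#' Read a GFF3 annotation file
#'
#' Parses the 9-column tab format. Coordinates are kept verbatim (1-based
#' inclusive, the package-wide convention); the attribute column is stored
#' as its raw string so key order survives a round trip. Comment and
#' directive lines (`#...`) are skipped.
#'
#' @param path path to a GFF3 file.
#' @return a data.frame of features with columns `seqid`, `source`, `type`,
#'   `start`, `end`, `score`, `strand`, `phase`, `attributes`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort("GFF3 file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_features())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != 9)) {
    abort("line %d: expected 9 tab-separated columns, found %d",
          lineno[which(ncols != 9)[1]], ncols[ncols != 9][1])
  }
  m <- matrix(unlist(parts), ncol = 9, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | m[, 4] != as.character(start) |
                 m[, 5] != as.character(end))
  if (length(bad) > 0) abort("line %d: non-integer coordinates", lineno[bad[1]])
  inv <- which(start > end)
  if (length(inv) > 0) abort("line %d: start > end", lineno[inv[1]])
  data.frame(seqid = m[, 1], source = m[, 2], type = m[, 3],
             start = start, end = end, score = m[, 6], strand = m[, 7],
             phase = m[, 8], attributes = m[, 9], stringsAsFactors = FALSE)
}

empty_features <- function() {
  data.frame(seqid = character(), source = character(), type = character(),
             start = integer(), end = integer(), score = character(),
             strand = character(), phase = character(),
             attributes = character(), stringsAsFactors = FALSE)
}

#' Write features to GFF3
#'
#' @param features a feature data.frame as returned by [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0) {
    writeLines(paste(features$seqid, features$source, features$type,
                     features$start, features$end, features$score,
                     features$strand, features$phase, features$attributes,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a GTF file into the GFF3 feature model
#'
#' Input-only convenience: GTF `key "value";` attributes are re-keyed to
#' GFF3 `key=value` pairs, with `gene_id`/`transcript_id` preserved under
#' their own names. Order of attributes is preserved.
#'
#' @param path path to a GTF file.
#' @return a feature data.frame as from [read_gff3()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort("GTF file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_features())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9)) abort("GTF requires 9 tab-separated columns")
  m <- matrix(unlist(parts), ncol = 9, byrow = TRUE)
  attrs <- vapply(m[, 9], function(a) {
    fields <- trimws(strsplit(a, ";", fixed = TRUE)[[1]])
    fields <- fields[nzchar(fields)]
    kv <- regmatches(fields, regexec('^(\\S+)\\s+"?([^"]*)"?$', fields))
    paste(vapply(kv, function(x) paste0(x[2], "=", x[3]), character(1)),
          collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  data.frame(seqid = m[, 1], source = m[, 2], type = m[, 3],
             start = as.integer(m[, 4]), end = as.integer(m[, 5]),
             score = m[, 6], strand = m[, 7], phase = m[, 8],
             attributes = attrs, stringsAsFactors = FALSE)
}

#' Extract one attribute key from GFF3 attribute strings
#'
#' @param features feature data.frame, or a character vector of raw
#'   attribute strings.
#' @param key attribute key, e.g. `"ID"` or `"Parent"`.
#' @return character vector of values; `NA` where the key is absent.
#' @export
gff_attr <- function(features, key) {
  attrs <- if (is.data.frame(features)) features$attributes else features
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}
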