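#' Read a FASTA file
#'
#' Sequences are uppercased on read; record order is preserved. The id is
#' the header token up to the first whitespace, the remainder (if any) is
#' kept as the description.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) abort("duplicate id %s", dup[[1]])
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    warnf("empty sequence for id(s): %s",
          paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `description` (appended to the header after a space when non-empty).
#' @param path output path.
#' @param line_width characters of sequence per line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  dup <- records$id[duplicated(records$id)]
  if (length(dup) > 0) abort("duplicate id %s", dup[[1]])
  hdr <- records$id
  if ("description" %in% names(records)) {
    has_desc <- !is.na(records$description) & nzchar(records$description)
    hdr[has_desc] <- paste(records$id[has_desc], records$description[has_desc])
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}
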