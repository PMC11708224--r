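#' @section AGP representation:
#' An AGP (A Golden Path) file describes how objects (scaffolds or
#' chromosomes) are tiled from oriented contig spans (`W` rows) and gap runs
#' (`N`/`U` rows). The package represents one as an object of class `"agp"`:
#' a list with a `rows` data.frame holding the nine AGP v2.1 columns
#' (component columns `NA` on gap rows and vice versa). All coordinates are
#' 1-based inclusive.
#' @name agp
NULL

KNOWN_GAP_TYPES <- c("scaffold", "contig", "centromere", "telomere",
                     "short_arm", "heterochromatin", "repeat", "contamination")

agp_cols <- c("object", "object_beg", "object_end", "part_number",
              "component_type", "component_id", "component_beg",
              "component_end", "orientation", "gap_length", "gap_type",
              "linkage", "linkage_evidence")

#' Construct and validate an AGP object
#'
#' Validates per-object tiling (rows cover `1..object_length` without holes
#' or overlap, part numbers consecutive from 1), span arithmetic on every
#' row, and file-wide uniqueness of `W` component ids.
#'
#' @param rows data.frame with the columns documented in [agp].
#' @return an object of class `"agp"`.
#' @export
new_agp <- function(rows) {
  stopifnot(is.data.frame(rows), all(agp_cols %in% names(rows)))
  rows <- rows[, agp_cols]
  validate_agp_rows(rows)
  structure(list(rows = rows), class = "agp")
}

validate_agp_rows <- function(rows) {
  if (nrow(rows) == 0) return(invisible(TRUE))
  if (!all(rows$component_type %in% c("W", "N", "U")))
    abort("component_type must be one of W, N, U")
  isw <- rows$component_type == "W"
  if (any(isw & (is.na(rows$component_id) | !nzchar(rows$component_id))))
    abort("W row missing component_id")
  if (any(isw & !(rows$orientation %in% c("+", "-"))))
    abort("W row orientation must be '+' or '-'")
  span_obj <- rows$object_end - rows$object_beg + 1
  span_cmp <- ifelse(isw, rows$component_end - rows$component_beg + 1,
                     rows$gap_length)
  bad <- which(span_obj != span_cmp | span_obj < 1)
  if (length(bad) > 0) {
    abort("object %s part %d: object span %d does not match %s span %d",
          rows$object[bad[1]], rows$part_number[bad[1]], span_obj[bad[1]],
          if (isw[bad[1]]) "component" else "gap", span_cmp[bad[1]])
  }
  if (any(isw & rows$component_beg < 1)) abort("component_beg must be >= 1")
  ids <- rows$component_id[isw]
  if (anyDuplicated(ids))
    abort("component %s used more than once", ids[duplicated(ids)][1])
  unknown <- setdiff(stats::na.omit(rows$gap_type[!isw]), KNOWN_GAP_TYPES)
  if (length(unknown) > 0)
    warnf("unknown AGP gap_type value(s): %s", paste(unknown, collapse = ", "))
  for (obj in unique(rows$object)) {
    r <- rows[rows$object == obj, ]
    if (!identical(as.integer(r$part_number), seq_len(nrow(r))))
      abort("object %s: part_numbers not consecutive from 1", obj)
    if (r$object_beg[1] != 1)
      abort("object %s part %d: tiling hole before first row", obj,
            r$part_number[1])
    if (nrow(r) > 1) {
      gap <- which(r$object_beg[-1] != r$object_end[-nrow(r)] + 1)
      if (length(gap) > 0) {
        abort("object %s part %d: tiling %s at object position %d", obj,
              r$part_number[gap[1] + 1],
              if (r$object_beg[gap[1] + 1] > r$object_end[gap[1]] + 1)
                "hole" else "overlap",
              r$object_beg[gap[1] + 1])
      }
    }
  }
  invisible(TRUE)
}

#' Object names and lengths of an AGP
#'
#' @param agp an [agp] object.
#' @return data.frame with columns `object`, `length`.
#' @export
agp_objects <- function(agp) {
  rows <- agp$rows
  objs <- unique(rows$object)
  len <- vapply(objs, function(o) max(rows$object_end[rows$object == o]),
                numeric(1))
  data.frame(object = objs, length = as.numeric(len), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.agp <- function(x, ...) {
  ob <- agp_objects(x)
  cat(sprintf("AGP: %d object(s), %d row(s), %s bp total\n",
              nrow(ob), nrow(x$rows),
              format(sum(ob$length), big.mark = ",")))
  invisible(x)
}

#' Read an AGP v2.1 file
#'
#' @param path path to a tab-separated AGP file; `#` comment lines allowed.
#' @return an [agp] object (invariants validated on read).
#' @export
read_agp <- function(path) {
  if (!file.exists(path)) abort("AGP file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(new_agp(empty_agp_rows()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9)) abort("AGP requires 9 tab-separated columns")
  m <- matrix(unlist(parts), ncol = 9, byrow = TRUE)
  isw <- m[, 5] == "W"
  rows <- data.frame(
    object = m[, 1],
    object_beg = as.numeric(m[, 2]),
    object_end = as.numeric(m[, 3]),
    part_number = as.integer(m[, 4]),
    component_type = m[, 5],
    component_id = ifelse(isw, m[, 6], NA_character_),
    component_beg = ifelse(isw, suppressWarnings(as.numeric(m[, 7])), NA_real_),
    component_end = ifelse(isw, suppressWarnings(as.numeric(m[, 8])), NA_real_),
    orientation = ifelse(isw, m[, 9], NA_character_),
    gap_length = ifelse(isw, NA_real_, suppressWarnings(as.numeric(m[, 6]))),
    gap_type = ifelse(isw, NA_character_, m[, 7]),
    linkage = ifelse(isw, NA_character_, m[, 8]),
    linkage_evidence = ifelse(isw, NA_character_, m[, 9]),
    stringsAsFactors = FALSE
  )
  new_agp(rows)
}

empty_agp_rows <- function() {
  data.frame(object = character(), object_beg = numeric(),
             object_end = numeric(), part_number = integer(),
             component_type = character(), component_id = character(),
             component_beg = numeric(), component_end = numeric(),
             orientation = character(), gap_length = numeric(),
             gap_type = character(), linkage = character(),
             linkage_evidence = character(), stringsAsFactors = FALSE)
}

#' Write an AGP object to file
#'
#' @param agp an [agp] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  stopifnot(inherits(agp, "agp"))
  r <- agp$rows
  isw <- r$component_type == "W"
  c6 <- ifelse(isw, r$component_id, format_bp(r$gap_length))
  c7 <- ifelse(isw, format_bp(r$component_beg), r$gap_type)
  c8 <- ifelse(isw, format_bp(r$component_end), r$linkage)
  c9 <- ifelse(isw, r$orientation, r$linkage_evidence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  if (nrow(r) > 0) {
    writeLines(paste(r$object, format_bp(r$object_beg), format_bp(r$object_end),
                     r$part_number, r$component_type, c6, c7, c8, c9,
                     sep = "\t"), con)
  }
  invisible(path)
}

format_bp <- function(x) sub("\\.0*$", "", format(x, scientific = FALSE, trim = TRUE))
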