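#' Convert a 3d-DNA scaffolding map to AGP
#'
#' Each scaffold in the map becomes one AGP object: alternating `W` rows
#' (orientation taken from the sign of the contig id) and `N` gap rows of
#' `gap_length` bp with gap type "scaffold", linkage "yes" and evidence
#' "proximity_ligation". Singleton contigs become single-`W` objects.
#'
#' @param map an `"assembly_map"` (see [read_assembly_map()]).
#' @param gap_length bp of gap between joined contigs (default 500, the
#'   common 3d-DNA export convention; 0 suppresses gap rows).
#' @param naming function mapping scaffold index to object name, or a
#'   character vector of names; default `scaffold_<i>`.
#' @return an [agp] object.
#' @export
assembly_map_to_agp <- function(map, gap_length = 500, naming = NULL) {
  stopifnot(inherits(map, "assembly_map"))
  if (any(map$entries$length <= 0))
    abort("zero-length entry %s in assembly map",
          map$entries$name[map$entries$length <= 0][1])
  nm <- stats::setNames(map$entries$name, map$entries$id)
  ln <- stats::setNames(map$entries$length, map$entries$id)
  if (is.null(naming)) naming <- function(i) sprintf("scaffold_%d", i)
  rows <- list()
  for (si in seq_along(map$scaffolds)) {
    ids <- map$scaffolds[[si]]
    obj <- if (is.function(naming)) naming(si) else naming[[si]]
    pos <- 1
    part <- 1L
    for (k in seq_along(ids)) {
      cid <- abs(ids[k])
      L <- ln[[as.character(cid)]]
      rows[[length(rows) + 1]] <- data.frame(
        object = obj, object_beg = pos, object_end = pos + L - 1,
        part_number = part, component_type = "W",
        component_id = nm[[as.character(cid)]], component_beg = 1,
        component_end = L, orientation = if (ids[k] < 0) "-" else "+",
        gap_length = NA_real_, gap_type = NA_character_,
        linkage = NA_character_, linkage_evidence = NA_character_,
        stringsAsFactors = FALSE)
      pos <- pos + L
      part <- part + 1L
      if (k < length(ids) && gap_length > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          object = obj, object_beg = pos, object_end = pos + gap_length - 1,
          part_number = part, component_type = "N",
          component_id = NA_character_, component_beg = NA_real_,
          component_end = NA_real_, orientation = NA_character_,
          gap_length = gap_length, gap_type = "scaffold", linkage = "yes",
          linkage_evidence = "proximity_ligation", stringsAsFactors = FALSE)
        pos <- pos + gap_length
        part <- part + 1L
      }
    }
  }
  new_agp(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Rebuild scaffold sequences from an AGP and its contigs
#'
#' `W` rows contribute the referenced contig slice (reverse-complemented
#' for `-` orientation); `N`/`U` rows contribute runs of `N`.
#'
#' @param agp an [agp] object.
#' @param contigs named character vector of contig sequences, or a
#'   data.frame with `id` and `sequence`.
#' @return data.frame with `id`, `description`, `sequence`, one row per
#'   AGP object, in AGP order.
#' @export
build_fasta_from_agp <- function(agp, contigs) {
  stopifnot(inherits(agp, "agp"))
  if (is.data.frame(contigs)) {
    contigs <- stats::setNames(contigs$sequence, contigs$id)
  }
  rows <- agp$rows
  objs <- unique(rows$object)
  seqs <- vapply(objs, function(obj) {
    r <- rows[rows$object == obj, , drop = FALSE]
    parts <- vapply(seq_len(nrow(r)), function(i) {
      if (r$component_type[i] == "W") {
        cid <- r$component_id[i]
        if (!cid %in% names(contigs)) abort("missing contig %s", cid)
        if (r$component_end[i] > nchar(contigs[[cid]]))
          abort("component_end %d exceeds length of contig %s (%d bp)",
                r$component_end[i], cid, nchar(contigs[[cid]]))
        piece <- substr(contigs[[cid]], r$component_beg[i], r$component_end[i])
        if (r$orientation[i] == "-") piece <- revcomp(piece)
        piece
      } else strrep("N", r$gap_length[i])
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  data.frame(id = objs, description = "", sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

# ---- curation edits ---------------------------------------------------------

# Internal editable form: ordered list object -> data.frame of components
# (W rows) with the gap that follows each one (NA after the last).
agp_to_components <- function(agp) {
  rows <- agp$rows
  objs <- unique(rows$object)
  comps <- lapply(objs, function(obj) {
    r <- rows[rows$object == obj, , drop = FALSE]
    isw <- r$component_type == "W"
    if (!isw[1] || !isw[nrow(r)] || any(!isw[-1] & !isw[-nrow(r)]))
      abort("object %s: leading, trailing or consecutive gap rows are not editable", obj)
    w <- which(isw)
    gap_after <- rep(NA_real_, length(w))
    gtype <- rep(NA_character_, length(w))
    glink <- rep(NA_character_, length(w))
    gev <- rep(NA_character_, length(w))
    for (k in seq_along(w)) {
      nxt <- w[k] + 1
      if (nxt <= nrow(r) && !isw[nxt]) {
        gap_after[k] <- r$gap_length[nxt]
        gtype[k] <- r$gap_type[nxt]
        glink[k] <- r$linkage[nxt]
        gev[k] <- r$linkage_evidence[nxt]
      }
    }
    data.frame(component_id = r$component_id[w],
               component_beg = r$component_beg[w],
               component_end = r$component_end[w],
               orientation = r$orientation[w],
               gap_after = gap_after, gap_type = gtype, linkage = glink,
               linkage_evidence = gev, stringsAsFactors = FALSE)
  })
  names(comps) <- objs
  comps
}

components_to_agp <- function(comps, default_gap = 500) {
  rows <- list()
  for (obj in names(comps)) {
    cf <- comps[[obj]]
    pos <- 1
    part <- 1L
    for (k in seq_len(nrow(cf))) {
      L <- cf$component_end[k] - cf$component_beg[k] + 1
      rows[[length(rows) + 1]] <- data.frame(
        object = obj, object_beg = pos, object_end = pos + L - 1,
        part_number = part, component_type = "W",
        component_id = cf$component_id[k],
        component_beg = cf$component_beg[k],
        component_end = cf$component_end[k],
        orientation = cf$orientation[k], gap_length = NA_real_,
        gap_type = NA_character_, linkage = NA_character_,
        linkage_evidence = NA_character_, stringsAsFactors = FALSE)
      pos <- pos + L
      part <- part + 1L
      if (k < nrow(cf)) {
        g <- cf$gap_after[k]
        if (is.na(g)) g <- default_gap
        if (g > 0) {
          gt <- if (is.na(cf$gap_type[k])) "scaffold" else cf$gap_type[k]
          gl <- if (is.na(cf$linkage[k])) "yes" else cf$linkage[k]
          ge <- if (is.na(cf$linkage_evidence[k])) "proximity_ligation"
                else cf$linkage_evidence[k]
          rows[[length(rows) + 1]] <- data.frame(
            object = obj, object_beg = pos, object_end = pos + g - 1,
            part_number = part, component_type = "N",
            component_id = NA_character_, component_beg = NA_real_,
            component_end = NA_real_, orientation = NA_character_,
            gap_length = g, gap_type = gt, linkage = gl,
            linkage_evidence = ge, stringsAsFactors = FALSE)
          pos <- pos + g
          part <- part + 1L
        }
      }
    }
  }
  new_agp(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

find_component <- function(comps, cid) {
  for (obj in names(comps)) {
    k <- which(comps[[obj]]$component_id == cid)
    if (length(k) == 1) return(list(object = obj, index = k))
  }
  NULL
}

#' Apply an ordered list of curation edits to an AGP
#'
#' Supported operations (each edit is a list with an `op` field):
#' \describe{
#'   \item{reorder}{`object`, `order` — permutation of the object's
#'     component ids.}
#'   \item{reorient}{`component` — flip one component's orientation.}
#'   \item{move}{`component`, `to`, `at` — remove a component from its
#'     object and insert it at position `at` (default: append) of object
#'     `to`; the source object is re-tiled with the gap collapsed.}
#'   \item{split}{`object`, `after`, `names` — split an object into two at
#'     the component boundary after component `after`.}
#'   \item{join}{`objects`, `name` — concatenate objects in the given
#'     order, separated by the default gap. The joined object keeps
#'     `name`, defaulting to the first object's name (the convention that a
#'     fusion keeps the lower-numbered chromosome label).}
#'   \item{rename}{`object`, `new` — rename an object.}
#' }
#' Edits apply sequentially, each to the result of the previous. The
#' returned liftover map sends every `W`-row base of the old assembly to
#' its position in the new one.
#'
#' @param agp an [agp] object.
#' @param edits list of edit operations.
#' @param default_gap gap inserted at junctions created by an edit (bp).
#' @return list with `agp` (new [agp]), `liftover` (data.frame
#'   `old_object`, `old_start`, `old_end`, `new_object`, `new_start`,
#'   `new_end`, `flipped`), and `log` (character, one entry per edit).
#' @export
apply_edits <- function(agp, edits = list(), default_gap = 500) {
  stopifnot(inherits(agp, "agp"))
  if (length(edits) == 0) {
    return(list(agp = agp, liftover = liftover_map(agp, agp), log = character()))
  }
  comps <- agp_to_components(agp)
  log <- character(length(edits))
  for (ei in seq_along(edits)) {
    ed <- edits[[ei]]
    op <- ed$op
    res <- tryCatch(
      switch(op,
        reorder = edit_reorder(comps, ed),
        reorient = edit_reorient(comps, ed),
        move = edit_move(comps, ed, default_gap),
        split = edit_split(comps, ed),
        join = edit_join(comps, ed, default_gap),
        rename = edit_rename(comps, ed),
        abort("unknown edit op '%s'", op)),
      error = function(e) abort("edit %d (%s): %s", ei, op, conditionMessage(e)))
    comps <- res$comps
    log[ei] <- res$log
  }
  new <- components_to_agp(comps, default_gap)
  list(agp = new, liftover = liftover_map(agp, new), log = log)
}

edit_reorder <- function(comps, ed) {
  cf <- comps[[ed$object]]
  if (is.null(cf)) abort("no such object %s", ed$object)
  if (!setequal(ed$order, cf$component_id) ||
      length(ed$order) != nrow(cf))
    abort("order is not a permutation of object %s components", ed$object)
  comps[[ed$object]] <- cf[match(ed$order, cf$component_id), , drop = FALSE]
  list(comps = comps,
       log = sprintf("reorder %s: %s", ed$object, paste(ed$order, collapse = ",")))
}

edit_reorient <- function(comps, ed) {
  loc <- find_component(comps, ed$component)
  if (is.null(loc)) abort("no such component %s", ed$component)
  cf <- comps[[loc$object]]
  cf$orientation[loc$index] <- if (cf$orientation[loc$index] == "+") "-" else "+"
  comps[[loc$object]] <- cf
  list(comps = comps, log = sprintf("reorient %s", ed$component))
}

edit_move <- function(comps, ed, default_gap) {
  loc <- find_component(comps, ed$component)
  if (is.null(loc)) abort("no such component %s", ed$component)
  if (is.null(comps[[ed$to]])) abort("no such target object %s", ed$to)
  cf <- comps[[loc$object]]
  row <- cf[loc$index, , drop = FALSE]
  row$gap_after <- NA_real_
  row$gap_type <- NA_character_
  row$linkage <- NA_character_
  row$linkage_evidence <- NA_character_
  cf <- cf[-loc$index, , drop = FALSE]
  if (nrow(cf) == 0) {
    comps[[loc$object]] <- NULL
  } else {
    cf$gap_after[nrow(cf)] <- NA_real_
    comps[[loc$object]] <- cf
  }
  tgt <- comps[[ed$to]]
  at <- if (is.null(ed$at)) nrow(tgt) + 1L else ed$at
  if (at < 1 || at > nrow(tgt) + 1) abort("insert index %d out of range", at)
  comps[[ed$to]] <- rbind(
    if (at > 1) tgt[seq_len(at - 1), , drop = FALSE],
    row,
    if (at <= nrow(tgt)) tgt[at:nrow(tgt), , drop = FALSE])
  list(comps = comps,
       log = sprintf("move %s to %s[%d]", ed$component, ed$to, at))
}

edit_split <- function(comps, ed) {
  cf <- comps[[ed$object]]
  if (is.null(cf)) abort("no such object %s", ed$object)
  k <- which(cf$component_id == ed$after)
  if (length(k) != 1) abort("no component %s in object %s", ed$after, ed$object)
  if (k == nrow(cf)) abort("cannot split after the last component")
  if (length(ed$names) != 2) abort("split needs two new names")
  left <- cf[seq_len(k), , drop = FALSE]
  left$gap_after[k] <- NA_real_
  right <- cf[(k + 1):nrow(cf), , drop = FALSE]
  pos <- match(ed$object, names(comps))
  out <- append(comps[-pos],
                stats::setNames(list(left, right), ed$names), after = pos - 1)
  list(comps = out,
       log = sprintf("split %s after %s into %s + %s", ed$object, ed$after,
                     ed$names[1], ed$names[2]))
}

edit_join <- function(comps, ed, default_gap) {
  if (any(!ed$objects %in% names(comps)))
    abort("no such object %s", setdiff(ed$objects, names(comps))[1])
  nm <- if (!is.null(ed$name)) ed$name else ed$objects[1]
  parts <- comps[ed$objects]
  for (i in seq_len(length(parts) - 1)) {
    parts[[i]]$gap_after[nrow(parts[[i]])] <- default_gap
  }
  joined <- do.call(rbind, c(unname(parts), list(make.row.names = FALSE)))
  pos <- match(ed$objects[1], names(comps))
  comps <- comps[!(names(comps) %in% ed$objects)]
  comps <- append(comps, stats::setNames(list(joined), nm),
                  after = min(pos - 1, length(comps)))
  list(comps = comps,
       log = sprintf("join %s as %s", paste(ed$objects, collapse = "+"), nm))
}

edit_rename <- function(comps, ed) {
  if (!ed$object %in% names(comps)) abort("no such object %s", ed$object)
  if (ed$new %in% names(comps)) abort("object %s already exists", ed$new)
  names(comps)[names(comps) == ed$object] <- ed$new
  list(comps = comps, log = sprintf("rename %s -> %s", ed$object, ed$new))
}

# Interval map old AGP -> new AGP, matched by (unique) component id.
liftover_map <- function(old, new) {
  ow <- old$rows[old$rows$component_type == "W", , drop = FALSE]
  nw <- new$rows[new$rows$component_type == "W", , drop = FALSE]
  m <- match(ow$component_id, nw$component_id)
  if (anyNA(m)) abort("component %s absent from new AGP",
                      ow$component_id[is.na(m)][1])
  data.frame(old_object = ow$object, old_start = ow$object_beg,
             old_end = ow$object_end, new_object = nw$object[m],
             new_start = nw$object_beg[m], new_end = nw$object_end[m],
             flipped = ow$orientation != nw$orientation[m],
             stringsAsFactors = FALSE)
}

#' Invert a liftover map
#'
#' @param map a liftover data.frame from [apply_edits()].
#' @return the inverse map (new coordinates become old and vice versa).
#' @export
invert_liftover <- function(map) {
  data.frame(old_object = map$new_object, old_start = map$new_start,
             old_end = map$new_end, new_object = map$old_object,
             new_start = map$old_start, new_end = map$old_end,
             flipped = map$flipped, stringsAsFactors = FALSE)
}

#' Lift annotation coordinates through an assembly edit
#'
#' Features fully inside one mapped interval are translated (with strand
#' flip and coordinate reversal on flipped intervals); feature lengths are
#' preserved exactly. A feature spanning a mapped-interval boundary is an
#' error by default — silent truncation would hide corruption — or is split
#' into parts sharing the original attributes when `split_features = TRUE`.
#' Features lying on unmapped (gap) bases are an error.
#'
#' @param features feature data.frame (see [read_gff3()]).
#' @param map liftover data.frame from [apply_edits()].
#' @param split_features split boundary-spanning features instead of
#'   erroring.
#' @return the lifted feature data.frame.
#' @export
liftover_features <- function(features, map, split_features = FALSE) {
  if (nrow(features) == 0) return(features)
  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    f <- features[i, , drop = FALSE]
    on_obj <- map[map$old_object == f$seqid, , drop = FALSE]
    inside <- which(on_obj$old_start <= f$start & f$end <= on_obj$old_end)
    if (length(inside) == 1) {
      out[[i]] <- lift_one(f, on_obj[inside, ])
      next
    }
    touching <- which(on_obj$old_start <= f$end & f$start <= on_obj$old_end)
    if (length(touching) == 0)
      abort("feature %s at %s:%d-%d lies on unmapped gap bases",
            gff_attr(f, "ID"), f$seqid, f$start, f$end)
    if (!split_features)
      abort("feature %s at %s:%d-%d spans a mapped-interval boundary",
            gff_attr(f, "ID"), f$seqid, f$start, f$end)
    parts <- lapply(touching, function(k) {
      iv <- on_obj[k, ]
      p <- f
      p$start <- max(f$start, iv$old_start)
      p$end <- min(f$end, iv$old_end)
      lift_one(p, iv)
    })
    out[[i]] <- do.call(rbind, parts)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

lift_one <- function(f, iv) {
  if (iv$flipped) {
    ns <- iv$new_start + (iv$old_end - f$end)
    ne <- iv$new_start + (iv$old_end - f$start)
    f$strand <- chartr("+-", "-+", f$strand)
  } else {
    ns <- iv$new_start + (f$start - iv$old_start)
    ne <- iv$new_start + (f$end - iv$old_start)
  }
  f$start <- ns
  f$end <- ne
  f$seqid <- iv$new_object
  f
}
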