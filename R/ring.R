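#' Aggregate pathways into a ring (sunburst) diagram
#'
#' Builds the prefix tree of pathway step sequences: the root is the primary
#' breast ring; each child ring shows the next site-set reached, with patient
#' counts and arc percentages relative to the full cohort (so sectors shrink
#' outward as patients stop progressing). Co-occurring site-sets become a
#' single sector labelled with the sorted sites joined by `+`
#' (e.g. `"bone+liver"`); death is a terminal `deceased` sector.
#'
#' @param pathways non-empty list of [pathway()] objects.
#' @param max_rings deepest ring to build (ring 0 is the primary).
#' @return A `"ring_node"` tree: nested lists with `site`, `ring`, `count`,
#'   `arc_pct`, `children`.
#' @examples
#' pw <- list(pathway(list("breast", "bone")),
#'            pathway(list("breast", "bone", "liver")),
#'            pathway(list("breast", "liver")))
#' build_ring_diagram(pw)
#' @export
build_ring_diagram <- function(pathways, max_rings = 7) {
  if (!length(pathways)) stop("non-empty pathway list required")
  if (max_rings < 1) stop("max_rings must be >= 1")
  total <- length(pathways)
  labels <- lapply(pathways, function(p)
    vapply(p$steps, site_set_label, character(1)))
  build <- function(idx, ring) {
    node_label <- if (ring == 0L) SITE_ORIGIN else
      labels[[idx[1L]]][ring + 1L]
    children <- list()
    if (ring < max_rings) {
      nxt <- vapply(idx, function(i)
        if (length(labels[[i]]) > ring + 1L) labels[[i]][ring + 2L]
        else NA_character_, character(1))
      has <- !is.na(nxt)
      if (any(has)) {
        groups <- split(idx[has], nxt[has])
        # deterministic child order: by count desc, then label
        ord <- order(-vapply(groups, length, integer(1)), names(groups))
        children <- lapply(names(groups)[ord], function(lab)
          build(groups[[lab]], ring + 1L))
      }
    }
    structure(list(site = node_label, ring = ring, count = length(idx),
                   arc_pct = 100 * length(idx) / total,
                   children = children),
              class = "ring_node")
  }
  build(seq_along(pathways), 0L)
}

#' @export
print.ring_node <- function(x, ...) {
  rec <- function(node, indent) {
    cat(strrep("  ", indent),
        sprintf("%s  ring %d  n=%d  (%.1f%%)\n", node$site, node$ring,
                node$count, node$arc_pct), sep = "")
    for (ch in node$children) rec(ch, indent + 1L)
  }
  rec(x, 0L)
  invisible(x)
}

ring_tree_to_df <- function(tree) {
  rows <- list()
  rec <- function(node, prefix) {
    path <- if (nzchar(prefix)) paste(prefix, node$site, sep = "|")
      else node$site
    rows[[length(rows) + 1L]] <<-
      data.frame(path = path, site = node$site, ring = node$ring,
                 count = node$count, arc_pct = node$arc_pct)
    for (ch in node$children) rec(ch, path)
  }
  rec(tree, "")
  do.call(rbind, rows)
}

#' Export or import a ring diagram
#'
#' `json` writes the nested sunburst document (`site`, `ring`, `count`,
#' `arc_pct`, `children`) consumable by standard hierarchy renderers; `csv`
#' writes one row per node with a `path` prefix column. Both formats
#' round-trip losslessly through [import_diagram()].
#'
#' @param tree a `"ring_node"` tree from [build_ring_diagram()].
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_diagram <- function(tree, path, format = c("json", "csv")) {
  stopifnot(inherits(tree, "ring_node"))
  format <- match.arg(format)
  if (format == "json") {
    strip <- function(node)
      list(site = node$site, ring = node$ring, count = node$count,
           arc_pct = node$arc_pct,
           children = lapply(node$children, strip))
    jsonlite::write_json(strip(tree), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(ring_tree_to_df(tree), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_diagram
#' @export
import_diagram <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    rebuild <- function(node)
      structure(list(site = node$site, ring = as.integer(node$ring),
                     count = as.integer(node$count),
                     arc_pct = as.numeric(node$arc_pct),
                     children = lapply(node$children, rebuild)),
                class = "ring_node")
    rebuild(doc)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$site <- as.character(df$site)
    rebuild <- function(p) {
      row <- df[df$path == p, ]
      kids <- df$path[df$ring == row$ring + 1L &
                        startsWith(df$path, paste0(p, "|")) &
                        !grepl("|", substring(df$path, nchar(p) + 2L),
                               fixed = TRUE)]
      # preserve file order of children
      structure(list(site = row$site, ring = as.integer(row$ring),
                     count = as.integer(row$count),
                     arc_pct = as.numeric(row$arc_pct),
                     children = lapply(kids, rebuild)),
                class = "ring_node")
    }
    rebuild(df$path[df$ring == 0L])
  }
}
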