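# Isocontour maps recorded along the evolution, inclusion trees over nested
# contours, node classification and minimum-nesting-depth saliency.

# Sub-pixel zero-level contours of a level-set field. Vertices are (row, col)
# pairs in 0-based pixel-center coordinates; polylines are closed (first
# vertex repeated last).
zero_contours <- function(phi, iteration = NA_integer_) {
  cl <- grDevices::contourLines(x = seq_len(nrow(phi)) - 1,
                                y = seq_len(ncol(phi)) - 1,
                                z = phi, levels = 0)
  lapply(cl, function(ct) {
    v <- cbind(row = ct$x, col = ct$y)
    if (v[1, 1] != v[nrow(v), 1] || v[1, 2] != v[nrow(v), 2]) {
      v <- rbind(v, v[1, , drop = FALSE])
    }
    list(vertices = v, iteration = iteration, area = polygon_area(v))
  })
}

# Shoelace area of a closed polygon given as an n x 2 matrix.
polygon_area <- function(v) {
  n <- nrow(v)
  x <- v[, 1]
  y <- v[, 2]
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# Even-odd ray-cast point-in-polygon test.
point_in_polygon <- function(pr, pc, v) {
  vr <- v[, 1]
  vc <- v[, 2]
  n <- length(vr)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vc[i] > pc) != (vc[j] > pc)) {
      xint <- (vr[j] - vr[i]) * (pc - vc[i]) / (vc[j] - vc[i]) + vr[i]
      if (pr < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Build an isocontour map from recorded level-set snapshots
#'
#' Extracts the closed zero-level contours of each snapshot and labels them
#' `C1, C2, ...` in recording order (outermost snapshots first). Snapshot
#' `i` is attributed to iteration `i * step` unless iteration numbers are
#' supplied.
#'
#' @param snapshots List of level-set fields (numeric matrices), or an
#'   `"spf_seg"` fit whose recorded snapshots are used.
#' @param step Recording interval in iterations (ignored when `snapshots`
#'   is a fit, which carries its own iteration numbers).
#' @return An object of class `"contour_map"`: a list of contours, each a
#'   list with `id`, `iteration`, `vertices` (n x 2, 0-based (row, col)
#'   pixel-center coordinates, closed) and `area` (enclosed, in pixels).
#' @export
build_contour_map <- function(snapshots, step = 1L) {
  if (inherits(snapshots, "spf_seg")) {
    iters <- snapshots$snapshot_iters
    snapshots <- snapshots$snapshots
  } else {
    iters <- step * seq_along(snapshots)
  }
  contours <- list()
  for (i in seq_along(snapshots)) {
    for (ct in zero_contours(snapshots[[i]], iters[i])) {
      ct$id <- sprintf("C%d", length(contours) + 1L)
      contours[[length(contours) + 1L]] <- ct
    }
  }
  structure(contours, class = "contour_map")
}

#' Isocontour map of a fitted segmentation
#'
#' Convenience wrapper: [build_contour_map()] on the snapshots a fit
#' recorded every `record_step` iterations.
#'
#' @param fit An `"spf_seg"` fit.
#' @return A `"contour_map"`.
#' @export
contour_map <- function(fit) {
  stopifnot(inherits(fit, "spf_seg"))
  build_contour_map(fit)
}

#' @export
print.contour_map <- function(x, ...) {
  cat(sprintf("Isocontour map: %d contours over %d recorded iterations\n",
              length(x), length(unique(vapply(x, `[[`, 0, "iteration")))))
  invisible(x)
}

#' Construct an inclusion tree from known topology
#'
#' Low-level constructor for an inclusion tree whose nesting structure is
#' already known (e.g. built by hand for analysis of a schematic map).
#' [build_inclusion_tree()] derives the topology geometrically instead.
#'
#' @param ids Character vector of contour labels.
#' @param parents Character vector, same length: parent label of each
#'   contour, `NA` for roots.
#' @param areas Optional numeric areas; children must not exceed parents.
#' @param iterations Optional integer recording iterations.
#' @param contours Optional list of contour records (with vertices).
#' @return An object of class `"inclusion_tree"`: a list with `nodes`, a
#'   data frame of `id`, `parent`, `area`, `iteration`, `class`, `depth`,
#'   and `contours`. Classes and depths are filled by [classify_nodes()].
#' @export
inclusion_tree <- function(ids, parents, areas = NULL, iterations = NULL,
                           contours = NULL) {
  stopifnot(length(ids) == length(parents), !anyDuplicated(ids))
  if (!all(is.na(parents) | parents %in% ids)) {
    stop("every non-NA parent must be one of `ids`", call. = FALSE)
  }
  if (any(!is.na(parents) & parents == ids)) {
    stop("a contour cannot enclose itself", call. = FALSE)
  }
  n <- length(ids)
  nodes <- data.frame(
    id = as.character(ids),
    parent = as.character(parents),
    area = if (is.null(areas)) rep(NA_real_, n) else areas,
    iteration = if (is.null(iterations)) rep(NA_integer_, n) else iterations,
    class = rep(NA_character_, n),
    depth = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, contours = contours),
            class = "inclusion_tree")
}

#' Build the inclusion tree of a contour map
#'
#' Derives the enclosure forest: the parent of a contour is the
#' smallest-area contour that strictly encloses it; contours enclosed by no
#' other are roots. Enclosure is decided by point-in-polygon tests of the
#' child's vertices against candidate parents (sorted by area); a pair of
#' contours that partially overlap — neither nested nor disjoint — raises a
#' topology-violation error, since the inward evolution can only produce
#' nested or disjoint contours. The one exception is a pair recorded at
#' different iterations: consecutive zero levels can cross by sub-pixel
#' extraction jitter when the front barely moves, so mixed point-in-polygon
#' votes across iterations are resolved by a vertex majority instead of
#' raising. Node classes and nesting depths are filled in via
#' [classify_nodes()].
#'
#' @param contours A `"contour_map"` or plain list of contour records.
#' @return An `"inclusion_tree"` with classified nodes.
#' @export
build_inclusion_tree <- function(contours) {
  n <- length(contours)
  ids <- vapply(seq_len(n), function(i) {
    if (is.null(contours[[i]]$id)) sprintf("C%d", i) else contours[[i]]$id
  }, "")
  areas <- vapply(contours, function(ct) {
    if (is.null(ct$area)) polygon_area(ct$vertices) else ct$area
  }, 0)
  iters <- vapply(contours, function(ct) {
    it <- ct$iteration
    if (is.null(it) || is.na(it)) NA_integer_ else as.integer(it)
  }, 0L)
  ord <- order(areas, decreasing = TRUE)
  parents <- rep(NA_character_, n)
  for (pos in seq_len(n)) {
    i <- ord[pos]
    # candidate parents: larger-area contours, smallest first
    cand <- rev(ord[seq_len(pos - 1L)])
    for (j in cand) {
      rel <- enclosure_relation(contours[[j]]$vertices,
                                contours[[i]]$vertices)
      if (rel == "overlap") {
        # contours recorded at different iterations of the inward
        # evolution are nested up to sub-pixel extraction jitter; a
        # majority of vertices decides. A genuine partial overlap within
        # one recording step is a topology violation.
        same_iter <- is.na(iters[i]) || is.na(iters[j]) ||
          iters[i] == iters[j]
        if (same_iter) {
          stop(sprintf(
            "topology violation: contours %s and %s partially overlap",
            ids[j], ids[i]), call. = FALSE)
        }
        frac <- enclosed_fraction(contours[[j]]$vertices,
                                  contours[[i]]$vertices)
        rel <- if (frac >= 0.5) "encloses" else "disjoint"
      }
      if (rel == "encloses") {
        parents[i] <- ids[j]
        break
      }
    }
  }
  tree <- inclusion_tree(ids, parents, areas = areas, iterations = iters,
                         contours = contours)
  classify_nodes(tree)
}

# Relation of polygon `outer` to polygon `inner`: "encloses", "disjoint" or
# "overlap" (partial). Tested on the inner polygon's vertices (last vertex
# skipped, it repeats the first).
enclosure_relation <- function(outer, inner) {
  frac <- enclosed_fraction(outer, inner)
  if (frac == 1) {
    "encloses"
  } else if (frac == 0) {
    "disjoint"
  } else {
    "overlap"
  }
}

# Fraction of `inner`'s vertices lying inside `outer`.
enclosed_fraction <- function(outer, inner) {
  m <- nrow(inner) - 1L
  inside <- vapply(seq_len(m), function(k) {
    point_in_polygon(inner[k, 1], inner[k, 2], outer)
  }, NA)
  mean(inside)
}

#' Classify inclusion-tree nodes and compute nesting depths
#'
#' Assigns each contour exactly one class: `branching` (two or more
#' children), `terminal` (no children — the contour stopped evolving),
#' `base` (single-child immediate descendant of a branching contour), and
#' `internal` for the remaining single-child chain nodes. Also fills the
#' `depth` column with each node's minimum nesting depth (see
#' [min_nesting_depth()]).
#'
#' @param tree An `"inclusion_tree"`.
#' @return The tree with `class` and `depth` columns completed.
#' @export
classify_nodes <- function(tree) {
  stopifnot(inherits(tree, "inclusion_tree"))
  nodes <- tree$nodes
  nchild <- vapply(nodes$id, function(id) {
    sum(!is.na(nodes$parent) & nodes$parent == id)
  }, 0L)
  parent_branching <- vapply(seq_len(nrow(nodes)), function(i) {
    p <- nodes$parent[i]
    !is.na(p) && nchild[match(p, nodes$id)] >= 2L
  }, NA)
  nodes$class <- ifelse(nchild >= 2L, "branching",
                        ifelse(nchild == 0L, "terminal",
                               ifelse(parent_branching, "base", "internal")))
  tree$nodes <- nodes
  tree$nodes$depth <- vapply(nodes$id, function(id) {
    min_nesting_depth(tree, id)
  }, 0L)
  tree
}

#' Minimum nesting depth of a contour
#'
#' The saliency score of the topographic analysis: the number of contours
#' along the shortest chain from the queried contour down to an innermost
#' (childless) contour, counting both ends, so an innermost contour has
#' depth 1 and the outer contour of a nested chain of three has depth 3.
#' For branching contours the minimum over descendant chains is taken. Base
#' contours with a large minimum nesting depth bound distinctive regions
#' with abrupt intensity change.
#'
#' @param tree An `"inclusion_tree"`.
#' @param id Contour label.
#' @return A positive integer.
#' @export
min_nesting_depth <- function(tree, id) {
  stopifnot(inherits(tree, "inclusion_tree"))
  nodes <- tree$nodes
  if (!id %in% nodes$id) {
    stop("unknown contour id: ", id, call. = FALSE)
  }
  depth_of <- function(node) {
    kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == node]
    if (length(kids) == 0L) {
      return(1L)
    }
    1L + min(vapply(kids, depth_of, 0L))
  }
  depth_of(id)
}

#' @export
print.inclusion_tree <- function(x, ...) {
  n <- nrow(x$nodes)
  roots <- sum(is.na(x$nodes$parent))
  cat(sprintf("Inclusion tree: %d contours, %d root(s)\n", n, roots))
  if (!all(is.na(x$nodes$class))) {
    tab <- table(x$nodes$class)
    cat("  classes:",
        paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a contour map and its inclusion tree as JSON
#'
#' Writes one JSON record per contour: `id`, `iteration`, `parent`, `class`,
#' `depth`, and `vertices` (n x 2 array of 0-based (row, col) pixel-center
#' coordinates).
#'
#' @param tree An `"inclusion_tree"` built from a contour map (so that
#'   vertex geometry is available), or a `"contour_map"` (exported without
#'   nesting fields).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_contour_map <- function(tree, path) {
  if (inherits(tree, "contour_map")) {
    tree <- build_inclusion_tree(tree)
  }
  stopifnot(inherits(tree, "inclusion_tree"))
  nodes <- tree$nodes
  recs <- lapply(seq_len(nrow(nodes)), function(i) {
    vert <- if (!is.null(tree$contours)) {
      v <- tree$contours[[i]]$vertices
      dimnames(v) <- NULL
      v
    } else {
      NULL
    }
    list(id = nodes$id[i],
         iteration = nodes$iteration[i],
         parent = nodes$parent[i],
         class = nodes$class[i],
         depth = nodes$depth[i],
         vertices = vert)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, na = "null",
                       digits = NA)
  invisible(path)
}
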