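# Decomposition of a reconstruction into soma-rooted process arbors and
# inter-junction branch segments, with centrifugal branch ordering.
#
# Conventions:
#   * All contiguous structure-code-1 points form the soma complex. Every
#     non-soma child of a soma point seeds one process arbor.
#   * If a cell carries no code-1 point, the root of the largest component is
#     used as a soma surrogate (with a warning): some tracing exports omit
#     soma codes and the analysis must not silently fail.
#   * Additional roots (detached fragments) each form one "fragment arbor";
#     their segments start at centrifugal order 1.
#   * A junction is any point with >= 2 children; the soma-attached segment
#     has order 1 and order increases by 1 at every junction, for every child
#     (centrifugal ordering, not Strahler).
#   * Zero-length duplicate points (< `merge_tolerance` um apart from their
#     parent) are merged into the parent before decomposition.

#' Decompose a reconstruction into arbors and branch segments
#'
#' Builds the topological decomposition underlying all morphometry: one
#' process arbor per neurite emanating from the soma (plus one arbor per
#' detached fragment), each arbor partitioned into inter-junction branch
#' segments carrying path length, centrifugal order, median radius and
#' straightness.
#'
#' @param recon An `swc_recon`.
#' @param merge_tolerance Parent-child pairs closer than this (micrometres,
#'   after `unit_scale`) are merged as duplicate tracing artifacts.
#' @return An object of class `ol_cell`: list with `points` (the merged
#'   points table plus a `row` index), `segments` (data frame; one row per
#'   branch segment with `segment_id`, `arbor_id`, `parent_segment`, `order`,
#'   `length_um`, `median_radius`, `straightness`, `n_points`, `is_tip`,
#'   `first_id`, `last_id`, and list columns `own_rows`, `chain_rows`),
#'   `arbors` (arbor index with `is_fragment`), `soma_rows`, `cell_id`,
#'   `unit_scale`, `n_components`, `fragment_count`, `soma_surrogate`.
#' @export
decompose_cell <- function(recon, merge_tolerance = 1e-6) {
  validate_swc(recon)
  pts <- recon$points
  us <- recon$unit_scale

  pts <- merge_duplicate_points(pts, merge_tolerance / us)
  n <- nrow(pts)
  parent_idx <- match(pts$parent, pts$id)

  children <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- parent_idx[i]
    if (!is.na(pi)) children[[pi]] <- c(children[[pi]], i)
  }
  children <- lapply(children, function(k) k[order(pts$id[k])])
  n_children <- lengths(children)

  soma_rows <- which(pts$type == 1L)
  soma_surrogate <- FALSE
  if (length(soma_rows) == 0) {
    root <- component_roots(pts)
    sizes <- table(root)
    big <- as.integer(names(sizes))[sizes == max(sizes)]
    # tie-break: smallest minimum sample id
    if (length(big) > 1) {
      min_id <- vapply(big, function(r) min(pts$id[root == r]), numeric(1))
      big <- big[which.min(min_id)]
    }
    soma_rows <- big[1]
    soma_surrogate <- TRUE
    warning("no structure-code-1 soma point in '", recon$cell_id,
            "': using root of largest component (sample ",
            pts$id[soma_rows], ") as soma surrogate", call. = FALSE)
  }
  is_soma <- rep(FALSE, n)
  is_soma[soma_rows] <- TRUE

  roots <- which(is.na(parent_idx))
  coords <- as.matrix(pts[, c("x", "y", "z")])

  segs <- list()        # accumulating segment records
  seg_parent <- integer(0)
  arbors <- list()
  arbor_assign <- rep(NA_integer_, n) # arbor per point row (NA = soma)

  walk_segment <- function(start, attach, order, arbor, parent_seg) {
    # chain: optional attach node (belongs to parent segment / soma) + run of
    # single-child points, ending at a junction, a tip, or a soma point.
    chain <- if (is.na(attach)) start else c(attach, start)
    own <- start
    cur <- start
    while (n_children[cur] == 1L && !is_soma[children[[cur]][1]]) {
      nxt <- children[[cur]][1]
      chain <- c(chain, nxt)
      own <- c(own, nxt)
      cur <- nxt
    }
    len <- polyline_length(coords[chain, , drop = FALSE]) * us
    sid <- length(segs) + 1L
    segs[[sid]] <<- list(
      arbor = arbor, order = order, own = own, chain = chain,
      length_um = len,
      median_radius = stats::median(pts$radius[own]) * us,
      straightness = if (len > 0)
        euclid(coords[chain[1], ], coords[chain[length(chain)], ]) * us / len
      else 1,
      n_points = length(own),
      is_tip = n_children[cur] == 0L,
      first_id = pts$id[own[1]], last_id = pts$id[cur]
    )
    seg_parent[sid] <<- parent_seg
    arbor_assign[own] <<- arbor
    # recurse into junction children (ascending id order)
    if (n_children[cur] >= 2L) {
      for (ch in children[[cur]]) {
        if (is_soma[ch]) next
        walk_segment(ch, cur, order + 1L, arbor, sid)
      }
    }
    invisible(NULL)
  }

  arbor_count <- 0L
  # Soma-attached arbors: each non-soma child of a soma point seeds one arbor.
  soma_children <- sort(unlist(lapply(soma_rows, function(s) {
    ch <- children[[s]]
    ch[!is_soma[ch]]
  })))
  soma_children <- soma_children[order(pts$id[soma_children])]
  for (ch in soma_children) {
    arbor_count <- arbor_count + 1L
    arbors[[arbor_count]] <- list(is_fragment = FALSE)
    walk_segment(ch, parent_idx[ch], 1L, arbor_count, NA_integer_)
  }
  # Fragment arbors: every remaining root that is not (surrogate) soma.
  frag_roots <- setdiff(roots, soma_rows)
  frag_roots <- frag_roots[order(pts$id[frag_roots])]
  for (r in frag_roots) {
    arbor_count <- arbor_count + 1L
    arbors[[arbor_count]] <- list(is_fragment = TRUE)
    if (n_children[r] >= 2L) {
      # broken stump with several continuations: each child starts an
      # order-1 segment; the stump point itself belongs to the arbor
      arbor_assign[r] <- arbor_count
      for (ch in children[[r]]) walk_segment(ch, r, 1L, arbor_count, NA_integer_)
    } else {
      walk_segment(r, NA_integer_, 1L, arbor_count, NA_integer_)
    }
  }

  if (length(segs) == 0)
    stop2("no branch segments: reconstruction '", recon$cell_id,
          "' contains only soma points")

  # Deterministic ordering: arbors by minimum own sample id, segments within
  # an arbor by (order, first own id).
  arbor_min_id <- vapply(seq_len(arbor_count), function(a) {
    rows <- which(arbor_assign == a)
    if (length(rows) == 0) Inf else min(pts$id[rows])
  }, numeric(1))
  arbor_rank <- match(seq_len(arbor_count), order(arbor_min_id))

  seg_df <- data.frame(
    arbor_id = arbor_rank[vapply(segs, `[[`, integer(1), "arbor")],
    order = vapply(segs, `[[`, integer(1), "order"),
    length_um = vapply(segs, `[[`, numeric(1), "length_um"),
    median_radius = vapply(segs, `[[`, numeric(1), "median_radius"),
    straightness = vapply(segs, `[[`, numeric(1), "straightness"),
    n_points = vapply(segs, `[[`, integer(1), "n_points"),
    is_tip = vapply(segs, `[[`, logical(1), "is_tip"),
    first_id = vapply(segs, `[[`, integer(1), "first_id"),
    last_id = vapply(segs, `[[`, integer(1), "last_id")
  )
  ord <- order(seg_df$arbor_id, seg_df$order, seg_df$first_id)
  seg_df <- seg_df[ord, , drop = FALSE]
  new_pos <- match(seq_along(segs), ord)
  seg_df$segment_id <- seq_len(nrow(seg_df))
  seg_df$parent_segment <- new_pos[seg_parent[ord]]
  seg_df$own_rows <- I(lapply(segs[ord], `[[`, "own"))
  seg_df$chain_rows <- I(lapply(segs[ord], `[[`, "chain"))
  rownames(seg_df) <- NULL
  seg_df <- seg_df[, c("segment_id", "arbor_id", "parent_segment", "order",
                       "length_um", "median_radius", "straightness",
                       "n_points", "is_tip", "first_id", "last_id",
                       "own_rows", "chain_rows")]

  arbor_df <- data.frame(
    arbor_id = seq_len(arbor_count),
    is_fragment = vapply(arbors, `[[`, logical(1), "is_fragment")[
      order(arbor_min_id)]
  )

  pts$row <- seq_len(n)
  ncomp <- length(unique(component_roots(pts)))
  structure(
    list(points = pts, segments = seg_df, arbors = arbor_df,
         soma_rows = soma_rows, arbor_of_point = arbor_rank[arbor_assign],
         cell_id = recon$cell_id, unit_scale = us,
         n_components = ncomp, fragment_count = ncomp - 1L,
         soma_surrogate = soma_surrogate),
    class = "ol_cell"
  )
}

# Merge parent-child point pairs closer than tol (coordinate units): the
# child is dropped and its children re-parented; a common tracing artifact.
merge_duplicate_points <- function(pts, tol) {
  repeat {
    parent_idx <- match(pts$parent, pts$id)
    has <- which(!is.na(parent_idx))
    if (length(has) == 0) return(pts)
    d <- sqrt((pts$x[has] - pts$x[parent_idx[has]])^2 +
              (pts$y[has] - pts$y[parent_idx[has]])^2 +
              (pts$z[has] - pts$z[parent_idx[has]])^2)
    dup <- has[d < tol]
    if (length(dup) == 0) return(pts)
    # merge one at a time to keep re-parenting simple (rare in practice)
    v <- dup[1]
    keep_id <- pts$id[parent_idx[v]]
    # never drop a soma point in favour of a neurite point
    if (pts$type[v] == 1L && pts$type[parent_idx[v]] != 1L)
      pts$type[parent_idx[v]] <- 1L
    pts$parent[pts$parent == pts$id[v]] <- keep_id
    pts <- pts[-v, , drop = FALSE]
  }
}

#' @export
print.ol_cell <- function(x, ...) {
  cat("Decomposed cell '", x$cell_id, "': ", nrow(x$arbors), " arbor(s), ",
      nrow(x$segments), " branch segment(s), max order ",
      max(x$segments$order), ", ", x$fragment_count, " fragment(s)\n",
      sep = "")
  invisible(x)
}

#' Path length of a branch segment
#'
#' Sum of consecutive 3-D Euclidean inter-point distances along the segment's
#' chain (including the link from the attachment node), scaled to
#' micrometres. A single-point segment has length 0 (with a warning).
#'
#' @param cell An `ol_cell` from [decompose_cell()].
#' @param segment_id Segment id.
#' @return Length in micrometres.
#' @export
segment_length <- function(cell, segment_id) {
  seg <- cell$segments[cell$segments$segment_id == segment_id, ]
  if (nrow(seg) == 0) stop2("no such segment: ", segment_id)
  chain <- seg$chain_rows[[1]]
  if (length(chain) < 2) {
    warning("single-point segment ", segment_id, ": length 0", call. = FALSE)
    return(0)
  }
  coords <- as.matrix(cell$points[chain, c("x", "y", "z")])
  polyline_length(coords) * cell$unit_scale
}

#' Per-arbor morphometrics
#'
#' For every process arbor: total path length, branch point count (junction
#' points, i.e. points with two or more children, excluding the soma),
#' maximum centrifugal order, segment and tip counts, and the longest
#' root-to-tip path length.
#'
#' @param cell An `ol_cell`.
#' @return Data frame with one row per arbor.
#' @export
arbor_metrics <- function(cell) {
  seg <- cell$segments
  # cumulative path length from arbor start to the end of each segment
  cum <- numeric(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    p <- seg$parent_segment[i]
    cum[i] <- seg$length_um[i] + if (is.na(p)) 0 else cum[p]
  }
  # junction points: own points with >= 2 children
  pts <- cell$points
  parent_idx <- match(pts$parent, pts$id)
  nch <- tabulate(parent_idx[!is.na(parent_idx)], nbins = nrow(pts))
  is_junction <- nch >= 2L
  is_junction[cell$soma_rows] <- FALSE

  out <- lapply(split(seq_len(nrow(seg)), seg$arbor_id), function(rows) {
    own <- unlist(seg$own_rows[rows])
    data.frame(
      arbor_id = seg$arbor_id[rows[1]],
      total_length_um = sum(seg$length_um[rows]),
      branch_point_count = sum(is_junction[own]),
      max_order = max(seg$order[rows]),
      segment_count = length(rows),
      tip_count = sum(seg$is_tip[rows]),
      longest_path_um = max(cum[rows][seg$is_tip[rows]],
                            cum[rows][length(rows)])
    )
  })
  res <- do.call(rbind, out)
  res <- merge(res, cell$arbors, by = "arbor_id", sort = TRUE)
  rownames(res) <- NULL
  res
}

#' Total branch count of a cell
#'
#' The paper-style "TB" denominator. Under mode `"all_segments"` every
#' inter-junction branch segment counts; under `"terminal_tips"` only
#' tip-terminated segments count. The per-arbor branch point and per-cell
#' branch counts reported for these cells are not mutually consistent under
#' any single definition, so the mode is explicit and recorded in outputs.
#'
#' @param cell An `ol_cell`.
#' @param mode `"all_segments"` (default) or `"terminal_tips"`.
#' @return Integer count.
#' @export
total_branches <- function(cell, mode = c("all_segments", "terminal_tips")) {
  mode <- match.arg(mode)
  if (mode == "all_segments") nrow(cell$segments)
  else sum(cell$segments$is_tip)
}

#' Cell-level morphometry summary
#'
#' Aggregates [arbor_metrics()] to one row per cell; both per-cell totals and
#' per-arbor means are emitted for branch points and length, since either
#' aggregation is used in the literature.
#'
#' @param cell An `ol_cell`.
#' @param tb_mode Branch-count mode, see [total_branches()].
#' @return One-row data frame.
#' @export
cell_morphometry <- function(cell, tb_mode = "all_segments") {
  am <- arbor_metrics(cell)
  data.frame(
    cell_id = cell$cell_id,
    n_points = nrow(cell$points),
    n_components = cell$n_components,
    fragment_count = cell$fragment_count,
    arbor_count = sum(!am$is_fragment),
    total_length_um = sum(am$total_length_um),
    mean_arbor_length_um = mean(am$total_length_um[!am$is_fragment]),
    mean_arbor_longest_path_um = mean(am$longest_path_um[!am$is_fragment]),
    total_branch_points = sum(am$branch_point_count),
    mean_branch_points_per_arbor = mean(am$branch_point_count[!am$is_fragment]),
    max_branch_order = max(am$max_order),
    total_branches = total_branches(cell, tb_mode),
    tb_mode = tb_mode
  )
}
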