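# Identification of putative internodes: myelinating process branches (M_PB)
# versus non-myelinating branches (NM_PB), and the derived summaries.
#
# Two classification modes:
#   * annotation: a segment is M_PB iff more than half of its own points
#     carry the internode structure code (used when reconstructions already
#     delimit internodes).
#   * criteria: an M_PB run is a maximal chain of same-thickness segments
#     that is (i) thick relative to its connecting (parent) branch,
#     (ii) long enough, and (iii) straight enough. The criteria are
#     reconstructions of the qualitative description of internodes as
#     thickened longitudinal membrane segments reached from fine connecting
#     branches; all thresholds are configurable and echoed into outputs.

#' Internode classification criteria
#'
#' @param mode `"auto"` (annotation mode when annotated points are present,
#'   criteria mode otherwise), `"annotation"`, or `"criteria"`.
#' @param annotation_code SWC structure code marking internode points
#'   (default 7).
#' @param min_length_um Minimum path length of a myelinating run, micrometres
#'   (default 25, just below the shortest putative internode observed in
#'   these preparations, ~29 um).
#' @param radius_ratio Minimum ratio of a run's starting median radius to its
#'   connecting (parent) branch median radius (default 2). For arbor-root
#'   segments, which have no parent branch, the cell-wide median of segment
#'   median radii is the reference.
#' @param min_straightness Minimum end-to-end distance / path length of the
#'   run (default 0.8; internodes are longitudinal).
#' @param thickness_tol A child segment continues a run if its median radius
#'   is within this factor of the run's starting radius (default 1.5).
#' @return An object of class `internode_criteria`.
#' @export
internode_criteria <- function(mode = c("auto", "annotation", "criteria"),
                               annotation_code = 7L,
                               min_length_um = 25,
                               radius_ratio = 2.0,
                               min_straightness = 0.8,
                               thickness_tol = 1.5) {
  mode <- match.arg(mode)
  stopifnot(min_length_um > 0, radius_ratio >= 1,
            min_straightness > 0, min_straightness <= 1, thickness_tol >= 1)
  structure(list(mode = mode, annotation_code = as.integer(annotation_code),
                 min_length_um = min_length_um, radius_ratio = radius_ratio,
                 min_straightness = min_straightness,
                 thickness_tol = thickness_tol),
            class = "internode_criteria")
}

#' @export
print.internode_criteria <- function(x, ...) {
  cat("Internode criteria: mode=", x$mode,
      ", annotation_code=", x$annotation_code,
      ", min_length_um=", x$min_length_um,
      ", radius_ratio=", x$radius_ratio,
      ", min_straightness=", x$min_straightness,
      ", thickness_tol=", x$thickness_tol, "\n", sep = "")
  invisible(x)
}

resolve_mode <- function(cell, criteria) {
  if (criteria$mode != "auto") return(criteria$mode)
  if (any(cell$points$type == criteria$annotation_code)) "annotation"
  else "criteria"
}

#' Classify branch segments as myelinating or non-myelinating
#'
#' Labels every branch segment of a decomposed cell `M_PB` (putative
#' internode member) or `NM_PB`.
#'
#' @param cell An `ol_cell` from [decompose_cell()].
#' @param criteria An [internode_criteria()] object.
#' @return A list with `class` (factor, one level per segment, levels
#'   `NM_PB`/`M_PB`), `run_id` (integer id of the myelinating run a segment
#'   belongs to, `NA` for NM_PB), and `mode_used`.
#' @export
classify_branches <- function(cell, criteria = internode_criteria()) {
  mode <- resolve_mode(cell, criteria)
  seg <- cell$segments
  ns <- nrow(seg)
  if (mode == "annotation") {
    anno <- cell$points$type == criteria$annotation_code
    if (!any(anno))
      stop2("annotation mode requested but no point carries structure code ",
            criteria$annotation_code,
            " (refusing to silently report zero internodes)")
    frac <- vapply(seg$own_rows, function(rows) mean(anno[rows]), numeric(1))
    is_m <- frac > 0.5
    run_id <- contiguous_runs(seg, is_m)
  } else {
    runs <- criteria_runs(cell, criteria)
    is_m <- rep(FALSE, ns)
    run_id <- rep(NA_integer_, ns)
    for (k in seq_along(runs)) {
      is_m[runs[[k]]] <- TRUE
      run_id[runs[[k]]] <- k
    }
  }
  list(class = factor(ifelse(is_m, "M_PB", "NM_PB"),
                      levels = c("NM_PB", "M_PB")),
       run_id = run_id, mode_used = mode)
}

# Group TRUE-labelled segments into maximal parent-child contiguous runs.
contiguous_runs <- function(seg, is_m) {
  run_id <- rep(NA_integer_, nrow(seg))
  nxt <- 0L
  for (i in order(seg$order, seg$segment_id)) {
    if (!is_m[i]) next
    p <- seg$parent_segment[i]
    if (!is.na(p) && is_m[p]) {
      run_id[i] <- run_id[p]
    } else {
      nxt <- nxt + 1L
      run_id[i] <- nxt
    }
  }
  run_id
}

# Criteria-mode run construction. A run starts at a segment whose median
# radius is >= radius_ratio times its connecting-branch reference (parent
# median radius, or the cell-wide median for arbor roots); it extends to the
# child of most similar thickness while the child stays within thickness_tol
# of the starting radius. A run is accepted (all members M_PB) iff total
# path length >= min_length_um and run straightness >= min_straightness.
criteria_runs <- function(cell, criteria) {
  seg <- cell$segments
  ns <- nrow(seg)
  med <- seg$median_radius
  cell_ref <- stats::median(med)
  parent_med <- ifelse(is.na(seg$parent_segment), cell_ref,
                       med[seg$parent_segment])
  starts <- which(med >= criteria$radius_ratio * parent_med)
  children_of <- split(seq_len(ns), factor(seg$parent_segment,
                                           levels = seq_len(ns)))
  coords <- as.matrix(cell$points[, c("x", "y", "z")])
  taken <- rep(FALSE, ns)
  runs <- list()
  for (s in starts[order(seg$order[starts], seg$segment_id[starts])]) {
    if (taken[s]) next
    members <- s
    r0 <- med[s]
    cur <- s
    repeat {
      kids <- children_of[[cur]]
      kids <- kids[!taken[kids] &
                   med[kids] <= criteria$thickness_tol * r0 &
                   med[kids] >= r0 / criteria$thickness_tol]
      if (length(kids) == 0) break
      # prefer the thickest continuation; ties broken by segment id
      cur <- kids[order(-med[kids], kids)][1]
      members <- c(members, cur)
    }
    len <- sum(seg$length_um[members])
    first_chain <- seg$chain_rows[[members[1]]]
    last_chain <- seg$chain_rows[[members[length(members)]]]
    stra <- if (len > 0)
      euclid(coords[first_chain[1], ],
             coords[last_chain[length(last_chain)], ]) *
        cell$unit_scale / len
    else 1
    if (len >= criteria$min_length_um && stra >= criteria$min_straightness) {
      taken[members] <- TRUE
      runs[[length(runs) + 1L]] <- members
    }
  }
  runs
}

#' Identify putative internodes
#'
#' Merges contiguous myelinating segments into internodes: M_PB segments on
#' one arbor that are parent-child contiguous form a single internode;
#' internodes separated by a non-myelinating connecting branch stay distinct.
#' Fine branches sprouting from an internode split it into contiguous
#' segments at the decomposition level but do not split the internode here.
#' An empty result is valid (the injury outcome).
#'
#' @param cell An `ol_cell`.
#' @param criteria An [internode_criteria()], or a precomputed classification
#'   from [classify_branches()].
#' @return Data frame with one row per internode: `internode_id`, `arbor_id`,
#'   `length_um` (path length of the merged run), `initiation_order`
#'   (centrifugal order of its first segment), `n_segments` and list column
#'   `segment_ids`; attribute `classification` holds the per-segment labels.
#' @export
identify_internodes <- function(cell, criteria = internode_criteria()) {
  cls <- if (is.list(criteria) && !inherits(criteria, "internode_criteria"))
    criteria
  else classify_branches(cell, criteria)
  seg <- cell$segments
  run_id <- if (cls$mode_used == "annotation")
    cls$run_id
  else contiguous_runs(seg, cls$class == "M_PB")
  ids <- sort(unique(run_id[!is.na(run_id)]))
  rows <- lapply(ids, function(k) which(run_id == k))
  out <- data.frame(
    arbor_id = vapply(rows, function(r) seg$arbor_id[r[1]], integer(1)),
    length_um = vapply(rows, function(r) sum(seg$length_um[r]), numeric(1)),
    initiation_order = vapply(rows, function(r) min(seg$order[r]), integer(1)),
    n_segments = lengths(rows)
  )
  ord <- order(out$arbor_id, out$initiation_order,
               vapply(rows, function(r) min(seg$segment_id[r]), integer(1)))
  out <- out[ord, , drop = FALSE]
  out$internode_id <- seq_len(nrow(out))
  out$segment_ids <- I(lapply(rows[ord], function(r) seg$segment_id[r]))
  rownames(out) <- NULL
  out <- out[, c("internode_id", "arbor_id", "length_um",
                 "initiation_order", "n_segments", "segment_ids")]
  attr(out, "classification") <- cls
  out
}

#' Internode summary for a cell
#'
#' Counts, length statistics, initiation-order statistics, the maximum number
#' of internodes supported by a single arbor, and the branch-class ratios
#' M_PB/TB and NM_PB/TB (which sum to 1 by construction: both use the same
#' TB denominator). With zero internodes the order statistics are `NA` but
#' the ratios remain defined.
#'
#' @param cell An `ol_cell`.
#' @param internodes Result of [identify_internodes()].
#' @param tb_mode Branch-count mode for the TB denominator.
#' @return One-row data frame.
#' @export
internode_summary <- function(cell, internodes, tb_mode = "all_segments") {
  cls <- attr(internodes, "classification")
  if (is.null(cls)) stop2("internodes must come from identify_internodes()")
  tb <- total_branches(cell, tb_mode)
  n_m <- sum(cls$class == "M_PB")
  m_ratio <- n_m / tb
  k <- nrow(internodes)
  per_arbor <- if (k > 0) max(table(internodes$arbor_id)) else 0L
  data.frame(
    cell_id = cell$cell_id,
    internode_count = k,
    mean_internode_length_um = if (k > 0) mean(internodes$length_um) else NA_real_,
    median_internode_length_um = if (k > 0) stats::median(internodes$length_um) else NA_real_,
    internode_length_q1_um = if (k > 0) unname(stats::quantile(internodes$length_um, 0.25)) else NA_real_,
    internode_length_q3_um = if (k > 0) unname(stats::quantile(internodes$length_um, 0.75)) else NA_real_,
    min_initiation_order = if (k > 0) min(internodes$initiation_order) else NA_integer_,
    max_initiation_order = if (k > 0) max(internodes$initiation_order) else NA_integer_,
    mean_initiation_order = if (k > 0) mean(internodes$initiation_order) else NA_real_,
    max_internodes_per_arbor = as.integer(per_arbor),
    m_pb_over_tb = m_ratio,
    nm_pb_over_tb = 1 - m_ratio,
    classification_mode = cls$mode_used
  )
}

#' Spatial envelope of the internode field
#'
#' Internodes of these cells run in parallel with the white-matter path and
#' occupy a flattened tube-like space. The envelope is summarised by the
#' first principal direction of the internode member points projected to the
#' XY plane (the in-plane tract axis), the extent of the points along the
#' in-plane direction orthogonal to that axis, and the extent along Z.
#'
#' @param cell An `ol_cell`.
#' @param internodes Result of [identify_internodes()]; must be non-empty.
#' @param fixed_axis Optional length-2 vector overriding the estimated
#'   in-plane axis (e.g. a known white-matter path direction).
#' @return List with `axis` (unit 2-vector, sign fixed to positive x, then
#'   positive y), `perpendicular_extent_um` and `z_extent_um`.
#' @export
spatial_envelope <- function(cell, internodes, fixed_axis = NULL) {
  if (nrow(internodes) == 0) stop2("no internodes: envelope undefined")
  seg <- cell$segments
  segs <- match(unlist(internodes$segment_ids), seg$segment_id)
  rows <- unique(unlist(seg$own_rows[segs]))
  xyz <- as.matrix(cell$points[rows, c("x", "y", "z")]) * cell$unit_scale
  if (is.null(fixed_axis)) {
    xy <- sweep(xyz[, 1:2, drop = FALSE], 2, colMeans(xyz[, 1:2, drop = FALSE]))
    cv <- crossprod(xy) / max(1, nrow(xy) - 1)
    ev <- eigen(cv, symmetric = TRUE)
    axis <- ev$vectors[, 1]
  } else {
    axis <- as.numeric(fixed_axis)
  }
  axis <- unit(axis)
  if (axis[1] < 0 || (axis[1] == 0 && axis[2] < 0)) axis <- -axis
  perp <- c(-axis[2], axis[1])
  proj <- xyz[, 1:2, drop = FALSE] %*% perp
  list(axis = axis,
       perpendicular_extent_um = diff(range(proj)),
       z_extent_um = diff(range(xyz[, 3])))
}
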