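# Reading, validating, writing and splitting SWC reconstructions.
#
# Dialect: 7 whitespace-separated columns (id, structure code, x, y, z,
# radius, parent), '#' comment lines, blank lines ignored, ids need not be
# consecutive. This matches NeuronStudio and Simple Neurite Tracer exports.

#' Read an SWC reconstruction
#'
#' Parses a plain-text SWC file into a validated `swc_recon` object. The
#' parent graph must be a forest: every `parent` is either -1 (a root) or an
#' existing sample id, ids are unique, radii positive and coordinates finite.
#' Fragmented cells (several roots, as produced by injury) are read as a
#' single reconstruction with multiple connected components.
#'
#' @param path Path to an SWC file.
#' @param cell_id Identifier for the cell; defaults to the file name without
#'   extension.
#' @param unit_scale Micrometres per coordinate unit (default 1: coordinates
#'   are already in micrometres).
#' @return An object of class `swc_recon`: a list with `points` (data frame
#'   with columns `id`, `type`, `x`, `y`, `z`, `radius`, `parent`),
#'   `cell_id`, `unit_scale` and `comments` (the file's `#` lines).
#' @seealso [write_swc()], [split_components()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".swc")
#' writeLines(c("# minimal cell", "1 1 0 0 0 5 -1", "2 3 10 0 0 0.4 1"), f)
#' read_swc(f)
read_swc <- function(path, cell_id = tools::file_path_sans_ext(basename(path)),
                     unit_scale = 1.0) {
  if (!file.exists(path)) stop2("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  comments <- lines[is_comment]
  keep <- which(!is_comment & nzchar(trimws(lines)))
  if (length(keep) == 0) stop2("no data lines in SWC file: ", path)

  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf != 7)
  if (length(bad) > 0)
    stop2("malformed SWC line ", keep[bad[1]], " in ", path,
          ": expected 7 columns, found ", nf[bad[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  nonnum <- which(apply(m, 1, function(r) any(is.na(r))))
  if (length(nonnum) > 0)
    stop2("malformed SWC line ", keep[nonnum[1]], " in ", path,
          ": non-numeric field")
  points <- data.frame(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5],
    radius = m[, 6], parent = as.integer(m[, 7])
  )
  recon <- structure(
    list(points = points, cell_id = cell_id,
         unit_scale = unit_scale, comments = comments),
    class = "swc_recon"
  )
  validate_swc(recon)
  recon
}

#' Construct an `swc_recon` from a points table
#'
#' @param points Data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @param cell_id Cell identifier.
#' @param unit_scale Micrometres per coordinate unit.
#' @param comments Character vector of `#` comment lines to carry along.
#' @return A validated `swc_recon`.
#' @export
swc_recon <- function(points, cell_id = "cell", unit_scale = 1.0,
                      comments = character()) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(points)))
    stop2("points must have columns: ", paste(need, collapse = ", "))
  points <- points[, need]
  points$id <- as.integer(points$id)
  points$type <- as.integer(points$type)
  points$parent <- as.integer(points$parent)
  recon <- structure(
    list(points = points, cell_id = cell_id,
         unit_scale = unit_scale, comments = comments),
    class = "swc_recon"
  )
  validate_swc(recon)
  recon
}

#' Validate an SWC reconstruction
#'
#' Checks the `swc_recon` invariants: unique ids, positive radii, finite
#' coordinates, every parent resolvable, and an acyclic parent graph with at
#' least one root.
#'
#' @param recon An `swc_recon`.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_swc <- function(recon) {
  p <- recon$points
  if (nrow(p) == 0) stop2("reconstruction has no points")
  if (anyDuplicated(p$id))
    stop2("duplicate sample id: ", p$id[duplicated(p$id)][1])
  if (any(!is.finite(p$x) | !is.finite(p$y) | !is.finite(p$z)))
    stop2("non-finite coordinates at sample ",
          p$id[which(!is.finite(p$x + p$y + p$z))[1]])
  if (any(!is.finite(p$radius) | p$radius <= 0))
    stop2("non-positive radius at sample ",
          p$id[which(!(p$radius > 0))[1]])
  has_parent <- p$parent != -1L
  idx <- match(p$parent[has_parent], p$id)
  if (anyNA(idx)) {
    bad <- p$id[has_parent][which(is.na(idx))[1]]
    stop2("dangling parent reference: sample ", bad,
          " points to absent parent ",
          p$parent[match(bad, p$id)])
  }
  if (!any(!has_parent)) stop2("no root point (parent -1) in reconstruction")
  parent_idx <- rep(NA_integer_, nrow(p))
  parent_idx[has_parent] <- idx
  # cycle check: follow parent chains with tri-state marking
  state <- integer(nrow(p)) # 0 = unseen, 1 = on stack, 2 = done
  for (s in seq_len(nrow(p))) {
    if (state[s] != 0L) next
    chain <- integer(0)
    v <- s
    while (!is.na(v) && state[v] == 0L) {
      state[v] <- 1L
      chain <- c(chain, v)
      v <- parent_idx[v]
    }
    if (!is.na(v) && state[v] == 1L)
      stop2("cycle in parent graph involving sample ", p$id[v])
    state[chain] <- 2L
  }
  invisible(recon)
}

#' Write an SWC reconstruction
#'
#' Writes an `swc_recon` back to the 7-column SWC dialect. Coordinates and
#' radii are written with 17 significant digits (full double precision), so
#' `read_swc(write_swc(x))` reproduces the points exactly.
#'
#' @param recon An `swc_recon` with at least one point.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(recon, path) {
  validate_swc(recon)
  p <- recon$points
  hdr <- recon$comments
  if (length(hdr) > 0) hdr <- ifelse(grepl("^\\s*#", hdr), hdr, paste("#", hdr))
  rows <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                  p$id, p$type, p$x, p$y, p$z, p$radius, p$parent)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Resolve, for every point, the row index of its component root.
component_roots <- function(points) {
  n <- nrow(points)
  parent_idx <- match(points$parent, points$id) # NA for roots
  root <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    chain <- integer(0)
    v <- s
    while (is.na(root[v]) && !is.na(parent_idx[v])) {
      chain <- c(chain, v)
      v <- parent_idx[v]
    }
    r <- if (is.na(parent_idx[v])) v else root[v]
    root[c(chain, v)] <- r
  }
  root
}

#' Split a reconstruction into connected components
#'
#' Partitions the points of a (possibly fragmented) reconstruction into its
#' connected components under the parent graph. Components are ordered by
#' their minimum sample id, so the ordering is deterministic.
#'
#' @param recon An `swc_recon`.
#' @return A list of `swc_recon` objects, one per component, with cell ids
#'   `"<cell_id>#<k>"`.
#' @export
split_components <- function(recon) {
  validate_swc(recon)
  p <- recon$points
  root <- component_roots(p)
  min_id <- tapply(p$id, root, min)
  comp_order <- names(sort(min_id))
  lapply(seq_along(comp_order), function(k) {
    rows <- which(root == as.integer(comp_order[k]))
    swc_recon(p[rows, , drop = FALSE],
              cell_id = paste0(recon$cell_id, "#", k),
              unit_scale = recon$unit_scale,
              comments = recon$comments)
  })
}

#' Number of connected components of a reconstruction
#'
#' @param recon An `swc_recon`.
#' @return Integer component count.
#' @export
n_components <- function(recon) {
  length(unique(component_roots(recon$points)))
}

#' Sample ids of soma points
#'
#' @param recon An `swc_recon`.
#' @return Integer vector of ids whose structure code is 1 (possibly empty).
#' @export
soma_ids <- function(recon) recon$points$id[recon$points$type == 1L]

#' @export
print.swc_recon <- function(x, ...) {
  cat("SWC reconstruction '", x$cell_id, "': ", nrow(x$points), " points, ",
      n_components(x), " component(s), ", length(soma_ids(x)),
      " soma point(s)\n", sep = "")
  invisible(x)
}
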