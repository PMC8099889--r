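# Independent oracles used across the suite. Each re-derives a quantity by a
# route different from the package implementation.

# Connected components by union-find over parent edges.
uf_components <- function(points) {
  n <- nrow(points)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- match(points$parent, points$id)
  for (i in seq_len(n)) {
    if (!is.na(idx[i])) {
      ri <- find(i); rj <- find(idx[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Centrifugal order of every point, by breadth-first labelling over the raw
# parent table: children of a soma point get order 1; order increases by one
# below every junction (point with >= 2 children).
point_orders <- function(points, soma_ids) {
  n <- nrow(points)
  idx <- match(points$parent, points$id)
  nch <- tabulate(idx[!is.na(idx)], nbins = n)
  is_soma <- points$id %in% soma_ids
  ord <- rep(NA_integer_, n)
  queue <- which(is_soma | is.na(idx))
  ord[queue] <- 0L
  ord[is.na(idx) & !is_soma] <- 1L # fragment roots start at order 1
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    kids <- which(idx == v & !is_soma)
    for (k in kids) {
      ord[k] <- if (is_soma[v]) 1L
        else ord[v] + (nch[v] >= 2L)
      queue <- c(queue, k)
    }
    # soma children of soma stay order 0
    skids <- which(idx == v & is_soma)
    for (k in skids) { ord[k] <- 0L; queue <- c(queue, k) }
  }
  ord
}

# Brute-force polyline length.
brute_length <- function(xyz) {
  s <- 0
  for (i in seq_len(nrow(xyz) - 1))
    s <- s + sqrt(sum((xyz[i + 1, ] - xyz[i, ])^2))
  s
}

# Exact two-sided Mann-Whitney p by full enumeration of rank arrangements.
mw_exact <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  n <- length(a); m <- length(b)
  u_obs <- sum(outer(a, b, ">"))
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(ix) {
    x <- pooled[ix]; y <- pooled[-ix]
    sum(outer(x, y, ">"))
  })
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# Brute-force in-plane principal direction: grid search over angles for the
# direction of maximal variance of the XY projection.
brute_axis <- function(xyz, n_grid = 20001) {
  xy <- sweep(xyz[, 1:2, drop = FALSE], 2, colMeans(xyz[, 1:2, drop = FALSE]))
  angles <- seq(0, pi, length.out = n_grid)
  v <- vapply(angles, function(a) mean((xy %*% c(cos(a), sin(a)))^2),
              numeric(1))
  a <- angles[which.max(v)]
  ax <- c(cos(a), sin(a))
  if (ax[1] < 0 || (ax[1] == 0 && ax[2] < 0)) ax <- -ax
  perp <- c(-ax[2], ax[1])
  list(axis = ax,
       perp_extent = diff(range(xyz[, 1:2, drop = FALSE] %*% perp)),
       z_extent = diff(range(xyz[, 3])))
}

# Independent criteria-mode classification: enumerate, for every segment that
# qualifies as a run start (median radius >= ratio x connecting-branch
# reference), its maximal same-thickness downward chain, and label the chain
# M_PB iff it meets the length and straightness thresholds. Mirrors the
# documented rule by direct enumeration over the segment table.
oracle_criteria_classes <- function(cell, criteria) {
  seg <- cell$segments
  med <- seg$median_radius
  ref <- stats::median(med)
  coords <- as.matrix(cell$points[, c("x", "y", "z")])
  n <- nrow(seg)
  label <- rep("NM_PB", n)
  claimed <- rep(FALSE, n)
  start_ok <- vapply(seq_len(n), function(i) {
    pref <- if (is.na(seg$parent_segment[i])) ref
      else med[seg$parent_segment[i]]
    med[i] >= criteria$radius_ratio * pref
  }, logical(1))
  ord <- order(seg$order, seg$segment_id)
  for (i in ord[start_ok[ord]]) {
    if (claimed[i]) next
    chain <- i
    repeat {
      tail_seg <- chain[length(chain)]
      kids <- which(!is.na(seg$parent_segment) &
                    seg$parent_segment == tail_seg &
                    !claimed &
                    med <= criteria$thickness_tol * med[i] &
                    med >= med[i] / criteria$thickness_tol)
      if (length(kids) == 0) break
      kids <- kids[order(-med[kids], kids)]
      chain <- c(chain, kids[1])
    }
    len <- sum(seg$length_um[chain])
    c1 <- seg$chain_rows[[chain[1]]]
    c2 <- seg$chain_rows[[chain[length(chain)]]]
    stra <- if (len > 0)
      sqrt(sum((coords[c1[1], ] - coords[c2[length(c2)], ])^2)) *
        cell$unit_scale / len else 1
    if (len >= criteria$min_length_um &&
        stra >= criteria$min_straightness) {
      label[chain] <- "M_PB"
      claimed[chain] <- TRUE
    }
  }
  label
}

# --- fixture builders --------------------------------------------------------

# swc_recon from a compact row specification.
recon_from_rows <- function(..., cell_id = "fixture") {
  rows <- list(...)
  m <- do.call(rbind, rows)
  swc_recon(data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                       z = m[, 5], radius = m[, 6], parent = m[, 7]),
            cell_id = cell_id)
}

# A straight annotated internode chain attached to a fine connecting branch:
# soma - fine branch (radius r_fine) - thick run (radius r_thick, `run_len`
# um along +x in `n_run` points, structure code `code`).
thick_run_recon <- function(run_len = 60, r_thick = 1.2, r_fine = 0.3,
                            n_run = 6, code = 7, cell_id = "run") {
  rows <- list(c(1, 1, 0, 0, 0, 5, -1))
  # fine connecting branch: 3 points, 6 um
  rows <- c(rows, list(c(2, 3, 2, 0, 0, r_fine, 1),
                       c(3, 3, 4, 0, 0, r_fine, 2),
                       c(4, 3, 6, 0, 0, r_fine, 3)))
  # a fine side branch at point 4 so the thick run starts at a junction
  rows <- c(rows, list(c(5, 3, 6, 2, 0, r_fine, 4),
                       c(6, 3, 6, 4, 0, r_fine, 5)))
  step <- run_len / n_run
  for (i in seq_len(n_run)) {
    rows <- c(rows, list(c(6 + i, code, 6 + i * step, 0, 0, r_thick,
                           if (i == 1) 4 else 5 + i)))
  }
  do.call(recon_from_rows, c(rows, list(cell_id = cell_id)))
}
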