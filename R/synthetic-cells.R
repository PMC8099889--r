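# Seeded synthetic oligodendrocyte morphologies with recorded ground truth.
#
# The generator emulates transitional oligodendrocytes in white matter:
# several process arbors radiate from the soma inside a flattened tube
# (the white-matter tract envelope); most branches are fine non-myelinating
# processes; a minority are putative internodes -- thick, long, nearly
# straight, tract-aligned branches reached from fine connecting branches.
# Internodes may chain (internode -> fine connector -> internode), sprout a
# fine internodal branch, or sit directly on the soma (order-1 initiations).
#
# All attachments (internode onto a fine branch, connector or sprout onto an
# internode, next internode onto a connector) are made at interior points of
# the host polyline, so every attachment is a proper SWC junction and the
# host splits into two branch segments at decomposition time.
#
# Preset calibration is analytic, not fitted: given the target number of
# internodes per cell and the target M_PB/TB ratio, closed-form expectations
# of the branching recursion determine the fine-tree size (see the methods
# vignette for the algebra). The per-cell internode count is drawn around
# its target with the cell-to-cell spread reported for these cells.

#' Expected number of branches in one fine process tree
#'
#' Under order-dependent bifurcation (probability `p0 * decay^(order-1)` of
#' splitting at the end of a branch of the given creation order, up to
#' `max_order`), the expected branch count is the sum of the branching
#' recursion `n_1 = 1`, `n_{o+1} = 2 p(o) n_o`.
#'
#' @param p0 Base bifurcation probability at order 1.
#' @param decay Per-order decay of the bifurcation probability.
#' @param max_order Maximum centrifugal order grown.
#' @return Expected branch count (>= 1).
#' @export
expected_fine_segments <- function(p0, decay = 0.8, max_order = 9) {
  n <- 1
  S <- 1
  for (o in seq_len(max_order - 1)) {
    n <- n * 2 * p0 * decay^(o - 1)
    S <- S + n
  }
  S
}

#' Morphology generator parameters
#'
#' Constructs the parameter set for [generate_cell()]. The two presets are
#' anchored to the reported morphometry of control and activity-silenced
#' (TTX) cerebellar cells: internode length median 84.7 um (IQR 68.6-101)
#' versus 53.8 um (39.3-81.2), M_PB/TB 0.28 versus 0.20, ~7.7 process arbors
#' per cell in both conditions (arbor morphology is unaffected by silencing),
#' and a total-branch count that comes out ~20% higher under TTX because the
#' extra branches fail to myelinate. Given `internodes_per_cell` and
#' `target_m_pb_ratio`, the fine-tree size and the internode placement
#' probability are solved in closed form from the branching expectations, so
#' a preset's configured targets are the generator's operating point rather
#' than tuned constants.
#'
#' @param preset `"control"` or `"ttx"`.
#' @param arbor_mean,arbor_sd,arbor_min Arbor count distribution: rounded
#'   normal, floored at `arbor_min`.
#' @param branch_decay,max_order Order-dependent bifurcation schedule.
#' @param fine_length_median,fine_length_sdlog Lognormal length of fine
#'   branches, micrometres.
#' @param fine_radius,internode_radius Branch radii, micrometres.
#' @param internodes_per_cell,target_m_pb_ratio Calibration targets (see
#'   Details).
#' @param internode_count_sd Cell-to-cell standard deviation of the internode
#'   count (default 1.5, matching the dispersion reported for these cells).
#' @param root_internode_prob Probability that an arbor's root branch is an
#'   internode (order-1 initiation, attached directly to the soma).
#' @param chain_prob Probability that an internode continues into a further
#'   internode via a fine connecting branch.
#' @param sprout_prob Probability that an internode carries one fine
#'   internodal sprout.
#' @param internode_length_median,internode_length_iqr Lognormal internode
#'   length: median and (Q1, Q3), micrometres.
#' @param axis_jitter_deg Angular jitter of internode directions around the
#'   tract axis (x), degrees.
#' @param envelope_perp,envelope_z Cross-section of the tract envelope that
#'   confines the cell, micrometres (perpendicular-to-tract by depth).
#' @param annotation_code Structure code written on internode points.
#' @param soma_radius Soma radius, micrometres.
#' @param step_fine,step_internode Tracing step (inter-point spacing), um.
#' @return An object of class `morph_params`.
#' @export
morph_params <- function(preset = c("control", "ttx"),
                         arbor_mean = 7.7, arbor_sd = 1.6, arbor_min = 3,
                         branch_decay = 0.8, max_order = 9,
                         fine_length_median = 12, fine_length_sdlog = 0.45,
                         fine_radius = 0.3, internode_radius = 1.2,
                         internodes_per_cell = NULL,
                         internode_count_sd = 1.5,
                         target_m_pb_ratio = NULL,
                         root_internode_prob = 0.30,
                         chain_prob = 0.40, sprout_prob = 0.25,
                         internode_length_median = NULL,
                         internode_length_iqr = NULL,
                         axis_jitter_deg = 5,
                         envelope_perp = 36.5, envelope_z = 17.33,
                         annotation_code = 7L, soma_radius = 5,
                         step_fine = 4, step_internode = 8) {
  preset <- match.arg(preset)
  if (preset == "control") {
    internodes_per_cell <- internodes_per_cell %||% 5.5
    target_m_pb_ratio <- target_m_pb_ratio %||% 0.28
    internode_length_median <- internode_length_median %||% 84.7
    internode_length_iqr <- internode_length_iqr %||% c(68.6, 101)
  } else {
    internodes_per_cell <- internodes_per_cell %||% 4.7
    target_m_pb_ratio <- target_m_pb_ratio %||% 0.20
    internode_length_median <- internode_length_median %||% 53.8
    internode_length_iqr <- internode_length_iqr %||% c(39.3, 81.2)
  }
  stopifnot(arbor_min >= 1, arbor_mean >= arbor_min,
            branch_decay > 0, branch_decay <= 1, max_order >= 2,
            fine_length_median > 0, internode_length_median > 0,
            internode_length_iqr[1] < internode_length_iqr[2],
            root_internode_prob >= 0, root_internode_prob <= 1,
            chain_prob >= 0, chain_prob < 1,
            sprout_prob >= 0, sprout_prob <= 1,
            target_m_pb_ratio > 0, target_m_pb_ratio < 1,
            envelope_perp > 0, envelope_z > 0)

  # --- analytic calibration -------------------------------------------------
  # Per cell: N internodes (drawn around internodes_per_cell with the
  # study-level spread internode_count_sd), grouped into chains of geometric
  # size (continuation probability chain_prob), E[chains] K = N (1 - c).
  # Chains sit at arbor roots (up to a Binomial(A, q1) number) or at interior
  # points of fine tree branches. Segment census: every internode is one
  # segment plus one split per connector attachment and per sprout, so
  # M = N (1 + s) + (N - K); fine overhead = tree-hosted chain splits
  # (K - n_root) + two connector halves per link + sprout stubs. The fine
  # tree size S per tree arbor then follows from the target ratio, and the
  # bifurcation probability p0 from the branching recursion.
  q1 <- root_internode_prob
  c_ <- chain_prob
  s_ <- sprout_prob
  A <- arbor_mean
  N <- internodes_per_cell
  K <- N * (1 - c_)
  n_root <- min(K, q1 * A)
  if (A - n_root < 1)
    stop2("infeasible parameters: no arbors left for fine trees")
  M_cell <- N * (1 + s_) + (N - K)
  tb_cell <- M_cell / target_m_pb_ratio
  fine_chain <- (K - n_root) + 2 * (N - K) + s_ * N
  S_needed <- (tb_cell - M_cell - fine_chain) / (A - n_root)
  if (S_needed < 1)
    stop2("infeasible parameters: target_m_pb_ratio ", target_m_pb_ratio,
          " cannot be reached (implied fine-tree size ",
          round(S_needed, 2), " < 1); lower the ratio or the chain overhead")
  f <- function(p0) expected_fine_segments(p0, branch_decay, max_order) - S_needed
  if (f(0.995) < 0)
    stop2("infeasible parameters: fine tree cannot grow large enough for ",
          "target_m_pb_ratio ", target_m_pb_ratio)
  branch_p0 <- stats::uniroot(f, c(1e-6, 0.995), tol = 1e-9)$root

  sdlog <- log(internode_length_iqr[2] / internode_length_iqr[1]) /
    (2 * stats::qnorm(0.75))
  structure(list(
    preset = preset,
    arbor_mean = arbor_mean, arbor_sd = arbor_sd, arbor_min = arbor_min,
    branch_p0 = branch_p0, branch_decay = branch_decay,
    max_order = as.integer(max_order),
    fine_length_median = fine_length_median,
    fine_length_sdlog = fine_length_sdlog,
    fine_radius = fine_radius, internode_radius = internode_radius,
    internodes_per_cell = internodes_per_cell,
    internode_count_sd = internode_count_sd,
    target_m_pb_ratio = target_m_pb_ratio,
    root_internode_prob = root_internode_prob,
    chain_prob = chain_prob, sprout_prob = sprout_prob,
    internode_length_median = internode_length_median,
    internode_length_iqr = internode_length_iqr,
    internode_length_sdlog = sdlog,
    axis_jitter_deg = axis_jitter_deg,
    envelope_perp = envelope_perp, envelope_z = envelope_z,
    annotation_code = as.integer(annotation_code),
    soma_radius = soma_radius,
    step_fine = step_fine, step_internode = step_internode
  ), class = "morph_params")
}

#' @export
print.morph_params <- function(x, ...) {
  cat("Morphology generator (", x$preset, " preset): ",
      x$arbor_mean, " arbors/cell, ", x$internodes_per_cell,
      " internodes/cell, internode median ", x$internode_length_median,
      " um, target M_PB/TB ", x$target_m_pb_ratio,
      " (p0=", round(x$branch_p0, 3), ")\n", sep = "")
  invisible(x)
}

# sample() without the scalar-x surprise
resample <- function(x) x[sample.int(length(x), 1)]

#' Generate one synthetic cell with ground truth
#'
#' Grows a seeded synthetic oligodendrocyte: arbors from the soma, fine
#' bifurcating trees, and internode chains placed per [morph_params()], all
#' confined to the tract envelope (directions reflect off the envelope walls
#' so path lengths are exact). Internode points carry the annotation
#' structure code and the internode radius. Identical seed and parameters
#' yield a byte-identical reconstruction.
#'
#' @param params A [morph_params()] object.
#' @param seed Integer seed (the generator restores the caller's RNG state).
#' @param cell_id Cell identifier.
#' @return List with `recon` (an `swc_recon`) and `truth` (class
#'   `morph_truth`): arbor count, per-branch table (`class`, `arbor`, point
#'   ids), per-internode table (realized `length_um`, `initiation_order`),
#'   expected segment census (`tb`, `m_pb_segments`), the realized internode
#'   envelope extents, and the parameters used.
#' @export
generate_cell <- function(params, seed = NULL,
                          cell_id = paste0("synth_", params$preset, "_",
                                           seed %||% "x")) {
  stopifnot(inherits(params, "morph_params"))
  P <- params
  with_seed(seed, {
    cap <- 1024L
    X <- Y <- Z <- R <- numeric(cap)
    TY <- PAR <- integer(cap)
    N <- 0L
    add_pt <- function(x, y, z, r, ty, parent) {
      if (N == length(X)) {
        X <<- c(X, numeric(cap)); Y <<- c(Y, numeric(cap))
        Z <<- c(Z, numeric(cap)); R <<- c(R, numeric(cap))
        TY <<- c(TY, integer(cap)); PAR <<- c(PAR, integer(cap))
      }
      N <<- N + 1L
      X[N] <<- x; Y[N] <<- y; Z[N] <<- z; R[N] <<- r
      TY[N] <<- ty; PAR[N] <<- parent
      N
    }
    branches <- list()
    new_branch <- function(class, arbor, ids) {
      branches[[length(branches) + 1L]] <<-
        list(class = class, arbor = arbor, pts = ids)
      invisible(NULL)
    }
    pt_xyz <- function(i) c(X[i], Y[i], Z[i])
    halfW <- P$envelope_perp / 2
    halfZ <- P$envelope_z / 2

    soma <- add_pt(0, 0, 0, P$soma_radius, 1L, -1L)

    # polyline of total length L from `start`, reflecting off the envelope
    # walls by flipping the direction component before stepping (so every
    # step keeps its exact length and the realized path length equals L)
    polyline <- function(parent_id, start, dir, L, step, wobble, r, ty,
                         min_pts = 3L) {
      n <- max(min_pts, ceiling(L / step))
      slen <- L / n
      ids <- integer(n)
      cur <- start
      d <- dir
      prev <- parent_id
      for (i in seq_len(n)) {
        d <- unit(d + stats::rnorm(3, 0, wobble))
        if (abs(cur[2] + d[2] * slen) > halfW) d[2] <- -d[2]
        if (abs(cur[3] + d[3] * slen) > halfZ) d[3] <- -d[3]
        cur <- cur + d * slen
        prev <- add_pt(cur[1], cur[2], cur[3], r, ty, prev)
        ids[i] <- prev
      }
      list(ids = ids, end = cur, dir = d)
    }

    rln <- function(median, sdlog) stats::rlnorm(1, log(median), sdlog)
    rand_dir <- function() unit(stats::rnorm(3) * c(2, 1, 0.5))

    # grow a chain of `g` internodes: internode, fine connector attached at
    # one of its interior points, next internode at an interior point of the
    # connector, and so on; each internode sprouts one fine internodal
    # branch with probability sprout_prob
    grow_internode_chain <- function(parent_id, start, g, arbor) {
      for (j in seq_len(g)) {
        L <- rln(P$internode_length_median, P$internode_length_sdlog)
        jit <- tan(P$axis_jitter_deg * pi / 180)
        dir <- unit(c(resample(c(-1, 1)),
                      stats::rnorm(1, 0, jit), stats::rnorm(1, 0, jit / 2)))
        pl <- polyline(parent_id, start, dir, L, P$step_internode, 0.02,
                       P$internode_radius, P$annotation_code, min_pts = 4L)
        new_branch("internode", arbor, pl$ids)
        interior <- pl$ids[2:(length(pl$ids) - 1L)]
        has_next <- j < g
        has_sprout <- stats::runif(1) < P$sprout_prob
        picks <- interior[sample.int(length(interior),
                                     min(length(interior),
                                         has_next + has_sprout))]
        k <- 0L
        if (has_sprout && length(picks) > k) {
          k <- k + 1L
          sp <- polyline(picks[k], pt_xyz(picks[k]), rand_dir(),
                         rln(P$fine_length_median, P$fine_length_sdlog),
                         P$step_fine, 0.25, P$fine_radius, 3L, min_pts = 2L)
          new_branch("fine", arbor, sp$ids)
        }
        if (!(has_next && length(picks) > k)) break
        k <- k + 1L
        conn <- polyline(picks[k], pt_xyz(picks[k]), rand_dir(),
                         rln(P$fine_length_median, P$fine_length_sdlog),
                         P$step_fine, 0.25, P$fine_radius, 3L, min_pts = 3L)
        new_branch("fine", arbor, conn$ids)
        attach <- resample(conn$ids[2:(length(conn$ids) - 1L)])
        parent_id <- attach
        start <- pt_xyz(attach)
      }
      invisible(NULL)
    }

    # pure fine bifurcating tree; branches recorded as chain hosts
    tree_branches <- integer(0) # indices into `branches` eligible as hosts
    grow_fine <- function(parent_id, start, dir, order, arbor) {
      L <- rln(P$fine_length_median, P$fine_length_sdlog)
      pl <- polyline(parent_id, start, dir, L, P$step_fine, 0.25,
                     P$fine_radius, 3L, min_pts = 3L)
      new_branch("fine", arbor, pl$ids)
      tree_branches <<- c(tree_branches, length(branches))
      if (order < P$max_order &&
          stats::runif(1) < P$branch_p0 * P$branch_decay^(order - 1)) {
        for (k in 1:2) {
          grow_fine(pl$ids[length(pl$ids)], pl$end,
                    unit(pl$dir + stats::rnorm(3, 0, 0.6)),
                    order + 1L, arbor)
        }
      }
      invisible(NULL)
    }

    A <- max(P$arbor_min, round(stats::rnorm(1, P$arbor_mean, P$arbor_sd)))
    # target internode count for this cell, split into geometric chains
    Ncount <- max(1L, as.integer(round(stats::rnorm(1, P$internodes_per_cell,
                                                    P$internode_count_sd))))
    sizes <- integer(0)
    rem <- Ncount
    while (rem > 0L) {
      g <- 1L
      while (g < rem && stats::runif(1) < P$chain_prob) g <- g + 1L
      sizes <- c(sizes, g)
      rem <- rem - g
    }
    n_root <- min(length(sizes), stats::rbinom(1, A, P$root_internode_prob),
                  A - 1L)
    # fine trees on the remaining arbors
    for (a in seq.int(n_root + 1L, A)) {
      grow_fine(soma, c(0, 0, 0), rand_dir(), 1L, a)
    }
    # root chains (order-1 initiations), then tree-hosted chains
    for (j in seq_len(length(sizes))) {
      if (j <= n_root) {
        grow_internode_chain(soma, c(0, 0, 0), sizes[j], j)
      } else {
        host <- if (length(tree_branches) >= 1)
          branches[[resample(tree_branches)]]
        else # no fine tree available: initiate from an existing internode
          branches[[resample(which(vapply(branches, `[[`, character(1),
                                          "class") == "internode"))]]
        at <- resample(host$pts[2:(length(host$pts) - 1L)])
        grow_internode_chain(at, pt_xyz(at), sizes[j], host$arbor)
      }
    }

    pts <- data.frame(id = seq_len(N), type = TY[1:N],
                      x = X[1:N], y = Y[1:N], z = Z[1:N],
                      radius = R[1:N], parent = PAR[1:N])
    recon <- swc_recon(pts, cell_id = cell_id,
                       comments = paste0("# synthetic cell (", P$preset,
                                         " preset, seed ",
                                         seed %||% "NA", ")"))

    truth <- build_truth(pts, branches, A, P, cell_id, soma)
    list(recon = recon, truth = truth)
  })
}

# Ground-truth bookkeeping from the final point table: centrifugal point
# orders (order increments below the soma and at every junction), the
# segment census (a segment starts at every child of the soma or of a
# junction), and per-internode realized lengths and initiation orders.
build_truth <- function(pts, branches, arbor_count, P, cell_id, soma_id) {
  n <- nrow(pts)
  nch <- tabulate(pts$parent[pts$parent > 0], nbins = n)
  ord <- integer(n)
  for (i in seq_len(n)[-1]) { # children are always created after parents
    p <- pts$parent[i]
    ord[i] <- if (p == soma_id) 1L else ord[p] + (nch[p] >= 2L)
  }
  is_start <- pts$parent == soma_id |
    (pts$parent > 0 & nch[pmax(pts$parent, 1)] >= 2L)
  is_start[soma_id] <- FALSE
  tb <- sum(is_start)
  m_pb_segments <- sum(is_start & pts$type == P$annotation_code)

  br <- data.frame(
    branch_id = seq_along(branches),
    class = vapply(branches, `[[`, character(1), "class"),
    arbor = vapply(branches, `[[`, integer(1), "arbor"),
    first_point = vapply(branches, function(b) b$pts[1], integer(1)),
    n_points = vapply(branches, function(b) length(b$pts), integer(1))
  )
  br$pts <- I(lapply(branches, `[[`, "pts"))

  ib <- which(br$class == "internode")
  xyz <- as.matrix(pts[, c("x", "y", "z")])
  internodes <- data.frame(
    internode_id = seq_along(ib),
    branch_id = br$branch_id[ib],
    arbor = br$arbor[ib],
    length_um = vapply(ib, function(b) {
      ids <- br$pts[[b]]
      polyline_length(xyz[c(pts$parent[ids[1]], ids), , drop = FALSE])
    }, numeric(1)),
    initiation_order = ord[br$first_point[ib]]
  )
  int_pts <- which(pts$type == P$annotation_code)
  envelope <- if (length(int_pts) > 0)
    c(perp = diff(range(pts$y[int_pts])), z = diff(range(pts$z[int_pts])))
  else c(perp = NA_real_, z = NA_real_)

  structure(list(
    cell_id = cell_id, arbor_count = arbor_count,
    branches = br, internodes = internodes,
    tb = tb, m_pb_segments = m_pb_segments,
    m_pb_ratio = m_pb_segments / tb,
    envelope = envelope,
    fragment_count = 0L,
    params = P
  ), class = "morph_truth")
}

#' @export
print.morph_truth <- function(x, ...) {
  cat("Ground truth '", x$cell_id, "': ", x$arbor_count, " arbors, ",
      nrow(x$internodes), " internodes, TB=", x$tb, ", M_PB/TB=",
      round(x$m_pb_ratio, 3), ", fragments=", x$fragment_count,
      "\n", sep = "")
  invisible(x)
}

#' Injury parameters
#'
#' @param fragment_detach_prob Probability that a branch is detached from its
#'   parent (becoming the root of a new disconnected component).
#' @param internode_deletion_prob Probability that an internode branch is
#'   deleted outright (default 1: complement-injured cells show no
#'   identifiable internodes).
#' @return An object of class `injury_params`.
#' @export
injury_params <- function(fragment_detach_prob = 0.3,
                          internode_deletion_prob = 1.0) {
  stopifnot(fragment_detach_prob >= 0, fragment_detach_prob <= 1,
            internode_deletion_prob >= 0, internode_deletion_prob <= 1)
  structure(list(fragment_detach_prob = fragment_detach_prob,
                 internode_deletion_prob = internode_deletion_prob),
            class = "injury_params")
}

#' Apply complement-style injury to a synthetic cell
#'
#' Emulates complement-mediated demyelinating injury: internode branches are
#' deleted (with their annotation codes), and surviving branches are
#' stochastically detached from their parents, producing the fragmented,
#' internode-free reconstructions seen after injury. Points whose parent was
#' deleted become new roots. Ground truth is updated accordingly
#' (`fragment_count` = number of connected components minus one).
#'
#' @param recon `swc_recon` from [generate_cell()].
#' @param truth Matching `morph_truth`.
#' @param params An [injury_params()] object.
#' @param seed Integer seed.
#' @return List with the fragmented `recon` and updated `truth`.
#' @export
apply_injury <- function(recon, truth, params = injury_params(),
                         seed = NULL) {
  stopifnot(inherits(params, "injury_params"), inherits(truth, "morph_truth"))
  with_seed(seed, {
    br <- truth$branches
    delete <- br$class == "internode" &
      stats::runif(nrow(br)) < params$internode_deletion_prob
    deleted_pts <- unlist(br$pts[delete])
    pts <- recon$points
    keep <- !(pts$id %in% deleted_pts)
    pts <- pts[keep, , drop = FALSE]
    orphan <- pts$parent %in% deleted_pts
    pts$parent[orphan] <- -1L
    # detach surviving branches at their first point
    surviving <- which(!delete)
    detach <- surviving[stats::runif(length(surviving)) <
                          params$fragment_detach_prob]
    fp <- br$first_point[detach]
    fp <- fp[fp %in% pts$id]
    pts$parent[match(fp, pts$id)] <- -1L

    recon2 <- swc_recon(pts, cell_id = paste0(recon$cell_id, "_injured"),
                        unit_scale = recon$unit_scale,
                        comments = c(recon$comments, "# complement injury"))
    n_comp <- n_components(recon2)
    truth2 <- truth
    truth2$cell_id <- recon2$cell_id
    truth2$branches$deleted <- delete
    truth2$internodes <- truth$internodes[
      !delete[truth$internodes$branch_id], , drop = FALSE]
    truth2$fragment_count <- n_comp - 1L
    truth2$tb <- NA_integer_
    truth2$m_pb_segments <- NA_integer_
    truth2$m_pb_ratio <- NA_real_
    list(recon = recon2, truth = truth2)
  })
}

#' Generate a cohort of synthetic cells
#'
#' @param n Number of cells.
#' @param params A [morph_params()] object.
#' @param seeds Integer vector of per-cell seeds (default `seed_base + 0:(n-1)`).
#' @param seed_base Base seed used when `seeds` is not given.
#' @param injury Optional [injury_params()] applied to every cell (injury
#'   seeds are the cell seeds offset by 500000).
#' @param dir Optional output directory: writes `<cell_id>.swc` per cell and
#'   a `ground_truth.json` summary.
#' @return List of per-cell lists (`recon`, `truth`).
#' @export
simulate_cohort <- function(n, params = morph_params("control"),
                            seeds = NULL, seed_base = 0L, injury = NULL,
                            dir = NULL) {
  seeds <- seeds %||% (seed_base + seq_len(n) - 1L)
  stopifnot(length(seeds) == n)
  out <- lapply(seq_len(n), function(i) {
    g <- generate_cell(params, seed = seeds[i])
    if (!is.null(injury))
      g <- apply_injury(g$recon, g$truth, injury, seed = seeds[i] + 500000L)
    g
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (g in out) write_swc(g$recon, file.path(dir, paste0(g$truth$cell_id,
                                                            ".swc")))
    gt <- lapply(out, function(g) list(
      cell_id = g$truth$cell_id,
      arbor_count = g$truth$arbor_count,
      internode_count = nrow(g$truth$internodes),
      internode_lengths_um = g$truth$internodes$length_um,
      initiation_orders = g$truth$internodes$initiation_order,
      tb = g$truth$tb, m_pb_segments = g$truth$m_pb_segments,
      fragment_count = g$truth$fragment_count
    ))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
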