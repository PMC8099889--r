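# Arbor decomposition, segment lengths, centrifugal ordering, branch counts.

test_that("simple topologies decompose as expected", {
  # soma with 3 unbranched chains: 3 arbors, no branch points, order 1
  r <- recon_from_rows(
    c(1, 1, 0, 0, 0, 5, -1),
    c(2, 3, 10, 0, 0, 1, 1), c(3, 3, 20, 0, 0, 1, 2),
    c(4, 3, 0, 10, 0, 1, 1), c(5, 3, 0, 20, 0, 1, 4),
    c(6, 3, 0, 0, 10, 1, 1), c(7, 3, 0, 0, 20, 1, 6))
  cell <- decompose_cell(r)
  am <- arbor_metrics(cell)
  expect_equal(nrow(am), 3)
  expect_equal(am$branch_point_count, c(0, 0, 0))
  expect_equal(am$max_order, c(1, 1, 1))
  expect_equal(total_branches(cell, "all_segments"), 3)
  expect_equal(total_branches(cell, "terminal_tips"), 3)

  # soma with one child that bifurcates once: 1 arbor, 1 branch point,
  # max order 2, 3 segments
  r2 <- recon_from_rows(
    c(1, 1, 0, 0, 0, 5, -1),
    c(2, 3, 10, 0, 0, 1, 1), c(3, 3, 20, 0, 0, 1, 2),
    c(4, 3, 30, 5, 0, 1, 3), c(5, 3, 30, -5, 0, 1, 3))
  cell2 <- decompose_cell(r2)
  am2 <- arbor_metrics(cell2)
  expect_equal(nrow(am2), 1)
  expect_equal(am2$branch_point_count, 1)
  expect_equal(am2$max_order, 2)
  expect_equal(am2$segment_count, 3)
  expect_equal(total_branches(cell2, "all_segments"), 3)
  expect_equal(total_branches(cell2, "terminal_tips"), 2)
})

test_that("segment lengths match hand values and a brute-force oracle", {
  r <- recon_from_rows(
    c(1, 1, 0, 0, 0, 5, -1),
    c(2, 3, 3, 4, 0, 1, 1))
  cell <- decompose_cell(r)
  expect_equal(segment_length(cell, 1), 5.0)

  r2 <- recon_from_rows(
    c(1, 1, 0, 0, 0, 5, -1),
    c(2, 3, 1, 0, 0, 1, 1), c(3, 3, 1, 1, 0, 1, 2), c(4, 3, 1, 1, 1, 1, 3))
  expect_equal(segment_length(decompose_cell(r2), 1), 3.0)

  # random 50-point polyline
  set.seed(42)
  xyz <- apply(matrix(rnorm(150), 50, 3), 2, cumsum)
  rows <- lapply(seq_len(50), function(i)
    c(i + 1, 3, xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, i))
  r3 <- do.call(recon_from_rows, c(list(c(1, 1, -5, -5, -5, 5, -1)), rows))
  cell3 <- decompose_cell(r3)
  expect_equal(segment_length(cell3, 1),
               brute_length(rbind(c(-5, -5, -5), xyz)))
})

test_that("a perfect binary tree of unit segments gives (7, 3, 3)", {
  # depth 3 from one soma child: 1 + 2 + 4 = 7 segments, each of length 1
  # (unit steps: horizontal offset dx, vertical dz = sqrt(1 - dx^2))
  rows <- list(c(1, 1, 0, 0, 0, 5, -1), c(2, 3, 0, 0, 1, 1, 1))
  nid <- 2
  level <- list(list(id = 2, x = 0, z = 1))
  for (d in 1:2) {
    nl <- list()
    for (nd in level) {
      for (s in c(-1, 1)) {
        nid <- nid + 1
        x <- nd$x + s * 2^(-d)
        z <- nd$z + sqrt(1 - (x - nd$x)^2)
        rows <- c(rows, list(c(nid, 3, x, 0, z, 1, nd$id)))
        nl <- c(nl, list(list(id = nid, x = x, z = z)))
      }
    }
    level <- nl
  }
  r <- do.call(recon_from_rows, rows)
  cell <- decompose_cell(r)
  am <- arbor_metrics(cell)
  expect_equal(am$segment_count, 7)
  expect_equal(am$total_length_um, 7, tolerance = 1e-9)
  expect_equal(am$branch_point_count, 3)
  expect_equal(am$max_order, 3)
  # unbranched arbor of length 40
  r2 <- recon_from_rows(c(1, 1, 0, 0, 0, 5, -1),
                        c(2, 3, 20, 0, 0, 1, 1), c(3, 3, 40, 0, 0, 1, 2))
  am2 <- arbor_metrics(decompose_cell(r2))
  expect_equal(c(am2$total_length_um, am2$branch_point_count, am2$max_order),
               c(40, 0, 1))
})

test_that("generated cells match ground truth and the order oracle", {
  for (s in c(2, 5, 9, 13)) {
    g <- generate_cell(morph_params("control"), seed = s)
    cell <- decompose_cell(g$recon)
    am <- arbor_metrics(cell)
    expect_equal(nrow(am), g$truth$arbor_count)
    expect_equal(total_branches(cell, "all_segments"), g$truth$tb)

    # point partition: arbor points + soma points = all points
    own <- unlist(cell$segments$own_rows)
    expect_equal(sort(c(own, cell$soma_rows)), seq_len(nrow(cell$points)))
    expect_equal(anyDuplicated(own), 0)

    # segment orders equal the independent point-order labelling
    ords <- point_orders(cell$points, cell$points$id[cell$soma_rows])
    for (i in seq_len(nrow(cell$segments))) {
      rows <- cell$segments$own_rows[[i]]
      expect_true(all(ords[rows] == cell$segments$order[i]))
    }

    # all junctions are binary in generated cells, so
    # TB(all_segments) = 2 * branch points + arbor roots
    expect_equal(total_branches(cell, "all_segments"),
                 2 * sum(am$branch_point_count) + nrow(am))
  }
})

test_that("unit_scale converts coordinates to micrometres", {
  r <- recon_from_rows(c(1, 1, 0, 0, 0, 5, -1), c(2, 3, 10, 0, 0, 1, 1))
  r$unit_scale <- 2.5
  cell <- decompose_cell(r)
  expect_equal(segment_length(cell, 1), 25)
  expect_equal(arbor_metrics(cell)$total_length_um, 25)
})

test_that("a soma-less cell falls back to a surrogate root with a warning", {
  r <- recon_from_rows(c(1, 3, 0, 0, 0, 1, -1),
                       c(2, 3, 10, 0, 0, 1, 1), c(3, 3, 20, 0, 0, 1, 2))
  expect_warning(cell <- decompose_cell(r), "surrogate")
  expect_true(cell$soma_surrogate)
  expect_equal(nrow(arbor_metrics(cell)), 1)
})

test_that("zero-length duplicate points are merged before decomposition", {
  r <- recon_from_rows(
    c(1, 1, 0, 0, 0, 5, -1),
    c(2, 3, 10, 0, 0, 1, 1),
    c(3, 3, 10, 0, 0, 1, 2),  # duplicate of 2
    c(4, 3, 20, 0, 0, 1, 3))
  cell <- decompose_cell(r)
  expect_equal(nrow(cell$points), 3)
  expect_equal(segment_length(cell, 1), 20)
})
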