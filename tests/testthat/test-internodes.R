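# Branch classification, internode identification, summaries, envelope.

test_that("criteria mode accepts a thick straight run and rejects a short one", {
  crit <- internode_criteria(mode = "criteria")
  cell <- decompose_cell(thick_run_recon(run_len = 60))
  cls <- classify_branches(cell, crit)
  seg <- cell$segments
  thick <- which(seg$median_radius > 1)
  expect_length(thick, 1)
  expect_equal(as.character(cls$class[thick]), "M_PB")
  expect_true(all(cls$class[-thick] == "NM_PB"))

  # identical geometry but 10 um long: below min_length_um
  cell10 <- decompose_cell(thick_run_recon(run_len = 10))
  cls10 <- classify_branches(cell10, crit)
  expect_true(all(cls10$class == "NM_PB"))
  expect_equal(nrow(identify_internodes(cell10, crit)), 0)
})

test_that("annotation mode errors when no points carry the code", {
  cell <- decompose_cell(thick_run_recon(code = 3))
  expect_error(
    classify_branches(cell, internode_criteria(mode = "annotation")),
    "no point carries")
})

test_that("contiguous annotated segments merge into one internode; an NM
           connector separates two", {
  # internode split by a sprout at an interior point: 2 M_PB segments but a
  # single internode whose length is the whole run
  r <- recon_from_rows(
    c(1, 1, 0, 0, 0, 5, -1),
    c(2, 7, 10, 0, 0, 1.2, 1), c(3, 7, 20, 0, 0, 1.2, 2),
    c(4, 7, 30, 0, 0, 1.2, 3), c(5, 7, 40, 0, 0, 1.2, 4),
    c(6, 3, 20, 5, 0, 0.3, 3), c(7, 3, 20, 10, 0, 0.3, 6))
  cell <- decompose_cell(r)
  crit <- internode_criteria(mode = "annotation")
  cls <- classify_branches(cell, crit)
  expect_equal(sum(cls$class == "M_PB"), 2)
  inter <- identify_internodes(cell, crit)
  expect_equal(nrow(inter), 1)
  expect_equal(inter$length_um, 40)
  expect_equal(inter$initiation_order, 1L)

  # two annotated runs joined by a fine connecting branch: 2 internodes
  # (the second run initiates at a junction partway along the connector)
  r2 <- recon_from_rows(
    c(1, 1, 0, 0, 0, 5, -1),
    c(2, 7, 15, 0, 0, 1.2, 1), c(3, 7, 30, 0, 0, 1.2, 2),
    c(4, 7, 45, 0, 0, 1.2, 3),
    c(5, 3, 30, 4, 0, 0.3, 3), c(6, 3, 30, 8, 0, 0.3, 5),
    c(9, 3, 30, 12, 0, 0.3, 6),
    c(7, 7, 45, 8, 0, 1.2, 6), c(8, 7, 60, 8, 0, 1.2, 7))
  cell2 <- decompose_cell(r2)
  inter2 <- identify_internodes(cell2, crit)
  expect_equal(nrow(inter2), 2)
  summ <- internode_summary(cell2, inter2)
  expect_equal(summ$internode_count, 2)
  expect_equal(summ$max_internodes_per_arbor, 2L)
})

test_that("summary order statistics and ratios follow their definitions", {
  g <- generate_cell(morph_params("control"), seed = 31)
  cell <- decompose_cell(g$recon)
  crit <- internode_criteria(mode = "annotation")
  inter <- identify_internodes(cell, crit)
  summ <- internode_summary(cell, inter)
  expect_equal(summ$min_initiation_order, min(inter$initiation_order))
  expect_equal(summ$max_initiation_order, max(inter$initiation_order))
  expect_equal(summ$mean_initiation_order, mean(inter$initiation_order))
  cls <- attr(inter, "classification")
  expect_equal(summ$m_pb_over_tb,
               sum(cls$class == "M_PB") / total_branches(cell))
  # the two ratios share the TB denominator and sum to one exactly
  expect_equal(summ$m_pb_over_tb + summ$nm_pb_over_tb, 1, tolerance = 1e-12)
})

test_that("NM_PB/TB + M_PB/TB is 1 across seeded cells and both modes", {
  for (s in 41:46) {
    g <- generate_cell(morph_params(if (s %% 2) "control" else "ttx"),
                       seed = s)
    cell <- decompose_cell(g$recon)
    for (mode in c("annotation", "criteria")) {
      inter <- identify_internodes(cell, internode_criteria(mode = mode))
      summ <- internode_summary(cell, inter)
      expect_equal(summ$m_pb_over_tb + summ$nm_pb_over_tb, 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("criteria-mode classification matches ground-truth annotations on
           >= 95% of segments across 100 seeded cells", {
  agree <- total <- 0
  for (s in 0:99) {
    g <- generate_cell(morph_params("control"), seed = s)
    cell <- decompose_cell(g$recon)
    truth_cls <- classify_branches(cell, internode_criteria(mode = "annotation"))
    crit_cls <- classify_branches(cell, internode_criteria(mode = "criteria"))
    agree <- agree + sum(truth_cls$class == crit_cls$class)
    total <- total + nrow(cell$segments)
  }
  expect_gt(agree / total, 0.95)
})

test_that("criteria-mode classification equals the exhaustive-run oracle", {
  crit <- internode_criteria(mode = "criteria")
  for (s in c(1, 4, 8, 15, 23, 57)) {
    g <- generate_cell(morph_params("control"), seed = s)
    cell <- decompose_cell(g$recon)
    if (nrow(cell$segments) > 50) next
    cls <- classify_branches(cell, crit)
    expect_equal(as.character(cls$class), oracle_criteria_classes(cell, crit))
  }
})

test_that("internode statistics are invariant to rigid motion", {
  g <- generate_cell(morph_params("control"), seed = 12)
  crit <- internode_criteria(mode = "annotation")
  base <- identify_internodes(decompose_cell(g$recon), crit)
  # rotation about z by 35 degrees plus a translation
  th <- 35 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  p <- g$recon$points
  xyz <- as.matrix(p[, c("x", "y", "z")]) %*% t(Rz)
  p$x <- xyz[, 1] + 100; p$y <- xyz[, 2] - 50; p$z <- xyz[, 3] + 5
  rot <- identify_internodes(decompose_cell(swc_recon(p)), crit)
  expect_equal(nrow(rot), nrow(base))
  expect_equal(rot$length_um, base$length_um, tolerance = 1e-6)
  expect_equal(rot$initiation_order, base$initiation_order)
})

test_that("deleting every annotated point yields zero internodes", {
  g <- generate_cell(morph_params("control"), seed = 18)
  inj <- apply_injury(g$recon, g$truth,
                      injury_params(fragment_detach_prob = 0,
                                    internode_deletion_prob = 1), seed = 1)
  a <- analyze_cell(inj$recon)
  expect_equal(a$cell$internode_count, 0)
  expect_equal(a$cell$classification_mode, "criteria") # no annotations left
  expect_true(is.na(a$cell$envelope_perp_um))
})

test_that("the spatial envelope matches a brute-force principal-direction
           oracle and handles degenerate input", {
  # soma away from the 4 internode points quoted below
  r <- recon_from_rows(
    c(1, 1, -5, 0, 0, 5, -1),
    c(2, 7, 0, 0, 0, 1.2, 1), c(3, 7, 10, 2, 1, 1.2, 2),
    c(4, 7, 20, -3, 2, 1.2, 3), c(5, 7, 30, 0, 0, 1.2, 4))
  cell <- decompose_cell(r)
  inter <- identify_internodes(cell, internode_criteria(mode = "annotation"))
  env <- spatial_envelope(cell, inter)
  pts <- rbind(c(0, 0, 0), c(10, 2, 1), c(20, -3, 2), c(30, 0, 0))
  oracle <- brute_axis(pts)
  expect_equal(env$axis, oracle$axis, tolerance = 1e-3)
  expect_gt(env$axis[1], 0.99) # tract axis is essentially +x
  expect_equal(env$perpendicular_extent_um, oracle$perp_extent,
               tolerance = 1e-3)
  expect_equal(env$perpendicular_extent_um, 4.4824, tolerance = 1e-3)
  expect_equal(env$z_extent_um, 2.0)

  # collinear points along x at z = 0: both extents are zero
  r2 <- recon_from_rows(
    c(1, 1, -5, 0, 0, 5, -1),
    c(2, 7, 0, 0, 0, 1.2, 1), c(3, 7, 10, 0, 0, 1.2, 2),
    c(4, 7, 20, 0, 0, 1.2, 3))
  cell2 <- decompose_cell(r2)
  inter2 <- identify_internodes(cell2, internode_criteria(mode = "annotation"))
  env2 <- spatial_envelope(cell2, inter2)
  expect_equal(env2$perpendicular_extent_um, 0, tolerance = 1e-9)
  expect_equal(env2$z_extent_um, 0)

  # zero internodes: explicit error
  cell3 <- decompose_cell(thick_run_recon(run_len = 10))
  inter3 <- identify_internodes(cell3, internode_criteria(mode = "criteria"))
  expect_error(spatial_envelope(cell3, inter3), "no internodes")
})

test_that("measured envelope extents recover the generated cross-section", {
  p <- morph_params("control")
  for (s in c(6, 14, 25)) {
    g <- generate_cell(p, seed = s)
    cell <- decompose_cell(g$recon)
    inter <- identify_internodes(cell, internode_criteria(mode = "annotation"))
    # along the generator's known tract axis (+x), the measured extents are
    # exactly the generated cross-section occupied by internode points
    env <- spatial_envelope(cell, inter, fixed_axis = c(1, 0))
    expect_equal(env$perpendicular_extent_um, unname(g$truth$envelope["perp"]),
                 tolerance = 1e-9)
    expect_equal(env$z_extent_um, unname(g$truth$envelope["z"]),
                 tolerance = 1e-9)
    # when the axis is estimated, it recovers the tract direction and the
    # depth extent stays within the configured envelope
    env2 <- spatial_envelope(cell, inter)
    expect_gt(env2$axis[1], 0.9)
    expect_lte(env2$z_extent_um, p$envelope_z + 1e-9)
  }
})
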