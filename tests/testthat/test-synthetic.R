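# Generator contracts: determinism, validity, parameter recovery hooks,
# injury semantics.

test_that("identical seeds reproduce byte-identical artifacts", {
  p <- morph_params("control")
  g1 <- generate_cell(p, seed = 0)
  g2 <- generate_cell(p, seed = 0)
  f1 <- tempfile(); f2 <- tempfile()
  write_swc(g1$recon, f1); write_swc(g2$recon, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g1$truth$internodes, g2$truth$internodes)
  g3 <- generate_cell(p, seed = 1)
  expect_false(identical(g1$recon$points, g3$recon$points))

  i1 <- generate_coloc_image(image_params(), seed = 0)
  i2 <- generate_coloc_image(image_params(), seed = 0)
  expect_identical(i1$nf200, i2$nf200)
  expect_identical(i1$truth$mbp_mask, i2$truth$mbp_mask)
})

test_that("the generator does not disturb the session RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_cell(morph_params("control"), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("generated cells are valid SWC with annotated internodes", {
  for (s in c(0, 8)) {
    g <- generate_cell(morph_params("ttx"), seed = s)
    expect_silent(validate_swc(g$recon))
    expect_equal(n_components(g$recon), 1)
    anno <- g$recon$points$type == 7
    int_pts <- unlist(g$truth$branches$pts[g$truth$branches$class ==
                                             "internode"])
    expect_setequal(g$recon$points$id[anno], int_pts)
    expect_true(all(g$recon$points$radius[anno] == 1.2))
  }
})

test_that("true internode lengths recover the configured median over a
           50-cell cohort", {
  p <- morph_params("control")
  lens <- unlist(lapply(0:49, function(s)
    generate_cell(p, seed = s)$truth$internodes$length_um))
  expect_lt(abs(median(lens) / p$internode_length_median - 1), 0.10)
  # and the spread matches the configured quartiles loosely
  expect_gt(stats::quantile(lens, 0.75), stats::quantile(lens, 0.25))
})

test_that("infeasible generator parameters are rejected at construction", {
  expect_error(morph_params("control", target_m_pb_ratio = 0.9),
               "infeasible")
  # a ratio this low would need a fine tree larger than the branching
  # schedule can ever produce
  expect_error(morph_params("control", target_m_pb_ratio = 0.05),
               "infeasible")
  expect_error(morph_params("control", internodes_per_cell = 60),
               "infeasible")
})

test_that("injury deletes internodes and detaches fragments as recorded", {
  p <- morph_params("control")
  g <- generate_cell(p, seed = 7)

  # no-op injury is the identity
  id0 <- apply_injury(g$recon, g$truth,
                      injury_params(fragment_detach_prob = 0,
                                    internode_deletion_prob = 0), seed = 1)
  expect_equal(id0$recon$points[, c("id", "type", "x", "parent")],
               g$recon$points[, c("id", "type", "x", "parent")])
  expect_equal(id0$truth$fragment_count, 0L)

  # full deletion: no annotated points survive, pipeline finds 0 internodes
  inj <- apply_injury(g$recon, g$truth,
                      injury_params(fragment_detach_prob = 0.3), seed = 7)
  expect_false(any(inj$recon$points$type == 7))
  a <- analyze_cell(inj$recon)
  expect_equal(a$cell$internode_count, 0)
  expect_equal(nrow(inj$truth$internodes), 0)

  # recorded fragment count matches both the package and the oracle
  expect_equal(n_components(inj$recon), inj$truth$fragment_count + 1L)
  expect_equal(uf_components(inj$recon$points), inj$truth$fragment_count + 1L)
  expect_equal(a$cell$fragment_count, inj$truth$fragment_count)
  expect_gt(inj$truth$fragment_count, 0)
})

test_that("simulate_cohort writes SWC files plus a readable truth sidecar", {
  dir <- file.path(tempdir(), "cohort_out")
  unlink(dir, recursive = TRUE)
  co <- simulate_cohort(3, morph_params("control"), seed_base = 70,
                        dir = dir)
  expect_length(list.files(dir, pattern = "\\.swc$"), 3)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(nrow(gt), 3)
  expect_equal(gt$arbor_count[1], co[[1]]$truth$arbor_count)
  # analysing the written files reproduces the in-memory truth census
  cohort <- analyze_swc_dir(dir, criteria = internode_criteria("annotation"))
  expect_equal(cohort$cells$total_branches,
               vapply(co, function(g) g$truth$tb, integer(1)))
  expect_equal(cohort$cells$internode_count,
               vapply(co, function(g) nrow(g$truth$internodes), integer(1)))
})

test_that("criteria configuration round-trips through YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("mode: criteria", "min_length_um: 30", "radius_ratio: 2.5",
               "unit_scale: 0.5", "tb_mode: terminal_tips"), f)
  cfg <- read_criteria_config(f)
  expect_equal(cfg$criteria$mode, "criteria")
  expect_equal(cfg$criteria$min_length_um, 30)
  expect_equal(cfg$criteria$radius_ratio, 2.5)
  expect_equal(cfg$unit_scale, 0.5)
  expect_equal(cfg$tb_mode, "terminal_tips")
})
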