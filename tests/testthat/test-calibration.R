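test_that("pixel scale is the mean of the two disc-dimension ratios", {
  expect_equal(estimate_pixel_scale(200, 200, 972, 972)$um_per_px, 4.86)
  expect_equal(estimate_pixel_scale(100, 100, 100, 100)$um_per_px, 1)
  expect_equal(estimate_pixel_scale(10, 10, 50, 40)$um_per_px, 4.5)
  expect_error(estimate_pixel_scale(-1, 10, 10, 10), "positive")
  expect_error(estimate_pixel_scale(0, 10, 10, 10), "positive")
})

test_that("caliber matches the brute-force oracle and nominal bar widths", {
  for (w in c(1, 3, 7, 15, 21, 31)) {
    for (ang in c(0, 30, 45, 90)) {
      bar <- make_bar(w, ang, size = 65)
      cm <- measure_caliber(bar, c(32, 32))
      oracle <- bf_caliber(bar$pixels, cm$point)
      expect_equal(cm$width_px, oracle, tolerance = 1e-9,
                   label = sprintf("width %d angle %d", w, ang))
      expect_lt(abs(cm$width_px - w), 1 + 1e-9,
                label = sprintf("nominal width %d angle %d: got %.2f",
                                w, ang, cm$width_px))
    }
  }
})

test_that("caliber converts to micrometers and flags background points", {
  bar <- make_bar(21, 0, size = 65)
  scale <- estimate_pixel_scale(100, 100, 100, 100)  # 1 um/px
  cm <- measure_caliber(bar, c(32, 32), scale)
  expect_equal(cm$width_um, cm$width_px)
  expect_lt(abs(cm$width_um - 21), 1 + 1e-9)  # smallest macular caliber class
  one <- make_bar(1, 0, size = 33)
  expect_equal(measure_caliber(one, c(16, 16))$width_px, 1)
  expect_error(measure_caliber(bar, c(1, 1)), "not a foreground")
})

test_that("vessel_tree validates forest structure", {
  nodes <- data.frame(id = 1:3, row = c(0, 10, 20), col = c(0, 0, 0))
  segs <- data.frame(parent = c(1, 2), child = c(2, 3), caliber = c(10, 8))
  expect_s3_class(vessel_tree(nodes, segs), "vessel_tree")
  bad <- data.frame(parent = c(1, 2, 3), child = c(2, 3, 2), caliber = 5)
  expect_error(vessel_tree(nodes, bad), "more than one parent")
  cyc <- data.frame(parent = c(1, 2, 3), child = c(2, 3, 1), caliber = 5)
  expect_error(vessel_tree(nodes, cyc), "cycle|parent")
})

test_that("generation rules follow diameter asymmetry at bifurcations", {
  mk <- function(cals) {
    # root segment then one bifurcation into two daughters
    nodes <- data.frame(id = 1:4, row = c(0, 10, 20, 20), col = c(0, 0, -5, 5))
    segs <- data.frame(parent = c(1, 2, 2), child = c(2, 3, 4), caliber = cals)
    assign_generations(vessel_tree(nodes, segs))$segments$generation
  }
  expect_equal(mk(c(20, 18, 8)), c(1L, 1L, 2L))   # asymmetric: trunk continues
  expect_equal(mk(c(20, 19, 19)), c(1L, 2L, 2L))  # symmetric: both advance
  # single unbranched root chain stays generation 1
  nodes <- data.frame(id = 1:4, row = 0:3 * 10, col = 0)
  segs <- data.frame(parent = 1:3, child = 2:4, caliber = c(10, 9.8, 9.6))
  expect_equal(assign_generations(vessel_tree(nodes, segs))$segments$generation,
               rep(1L, 3))
})

test_that("a chain of k asymmetric bifurcations reaches generation k + 1", {
  for (k in 1:6) {
    # follow the smaller daughter through k strictly asymmetric bifurcations
    nodes <- data.frame(id = 1:2, row = c(0, 10), col = 0)
    segs <- data.frame(parent = 1, child = 2, caliber = 60)
    nid <- 2L
    tip <- 2L
    cal <- 60
    for (i in seq_len(k)) {
      big <- nid + 1L
      small <- nid + 2L
      nodes <- rbind(nodes,
                     data.frame(id = c(big, small), row = i * 10 + 10,
                                col = c(-i * 5, i * 5)))
      segs <- rbind(segs,
                    data.frame(parent = tip, child = c(big, small),
                               caliber = c(cal * 0.95, cal * 0.5)))
      tip <- small
      nid <- nid + 2L
      cal <- cal * 0.5
    }
    tr <- assign_generations(vessel_tree(nodes, segs))
    expect_equal(max(tr$segments$generation), k + 1L)
  }
})

test_that("generations are recovered from calibers on simulated trees", {
  hits <- vapply(1:10, function(s) {
    p <- tree_sim_params(seed = s, window = 512, asymmetry = c(0.45, 0.7))
    sim <- simulate_tree(p, raster = FALSE)
    rec <- assign_generations(sim$tree)
    mean(rec$segments$generation == sim$tree$segments$generation)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
  # generations never decrease from parent to child
  sim <- simulate_tree(tree_sim_params(seed = 2, window = 512), raster = FALSE)
  seg <- assign_generations(sim$tree)$segments
  gen_of <- setNames(seg$generation, seg$child)
  parents_gen <- gen_of[as.character(seg$parent)]
  ok <- is.na(parents_gen) | seg$generation >= parents_gen
  expect_true(all(ok))
})

test_that("vessel trees round-trip through JSON", {
  sim <- simulate_tree(tree_sim_params(seed = 4, window = 256), raster = FALSE)
  tree <- assign_generations(sim$tree)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(tree, path)
  back <- read_tree(path)
  expect_equal(back$segments$generation, tree$segments$generation)
  expect_equal(back$nodes$row, tree$nodes$row)
})
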