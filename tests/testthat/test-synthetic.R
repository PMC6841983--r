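test_that("fractal fixtures have exact closed-form foreground counts", {
  expect_equal(sum(make_fractal("sierpinski_carpet", 3, 729)$pixels), 373248)
  expect_equal(sum(make_fractal("sierpinski_carpet", 2, 81)$pixels),
               64 * 9^2)
  expect_equal(sum(make_fractal("line", side = 512)$pixels), 512)
  expect_equal(sum(make_fractal("filled_square", side = 64)$pixels), 4096)
  expect_error(make_fractal("sierpinski_carpet", 3, 100), "3\\^k")
})

test_that("tree simulation is bit-reproducible and respects parameter bounds", {
  p <- test_tree_params(7, window = 256)
  a <- simulate_tree(p)
  b <- simulate_tree(p)
  expect_identical(a$mask$pixels, b$mask$pixels)
  expect_identical(a$tree$segments, b$tree$segments)
  expect_error(tree_sim_params(taper = 1.2), "taper")
  expect_error(tree_sim_params(window = 32), "window")
  expect_error(tree_sim_params(asymmetry = c(0.9, 0.4)), "asymmetry")
  expect_error(tree_sim_params(branch_prob = 1.4), "probabilities")
})

test_that("calibers taper geometrically across generations", {
  # near-symmetric branching so the taper factor dominates caliber decay
  p <- tree_sim_params(seed = 5, window = 512, root_caliber = 20, taper = 0.7,
                       asymmetry = c(0.85, 0.99), branch_prob = 0.6,
                       min_caliber = 1, segment_length = c(30, 8))
  sim <- simulate_tree(p, raster = FALSE)
  seg <- sim$tree$segments
  expect_lte(max(seg$generation), 5)
  g5 <- seg$caliber[seg$generation == 5]
  expect_gt(length(g5), 0)
  # 20 * 0.7^4 = 4.8 expected at generation 5 before decay noise
  expect_lt(abs(mean(g5) - 20 * 0.7^4) / (20 * 0.7^4), 0.35)
})

test_that("an avascular zone stays vessel-free and trees stay connected", {
  p <- tree_sim_params(seed = 11, window = 256, faz_radius = 30,
                       root_pos = c(128, 20), root_dirs = 0,
                       segment_length = c(30, 8), root_caliber = 10)
  sim <- simulate_tree(p)
  fg <- which(sim$mask$pixels, arr.ind = TRUE) - 1
  ctr <- (256 - 1) / 2
  expect_gt(min(sqrt((fg[, 1] - ctr)^2 + (fg[, 2] - ctr)^2)), 30)
  expect_equal(n_components(sim$mask), 1)
})

test_that("single-root trees rasterize to one 8-connected component", {
  for (s in 1:5) {
    sim <- simulate_tree(test_tree_params(s, window = 256))
    expect_equal(n_components(sim$mask), 1, info = paste("seed", s))
  }
})

test_that("region archetypes show the healthy macula-vs-disc contrast", {
  st <- function(m) suppressWarnings({
    sk <- skeletonize(m)
    c(d = vessel_density(sk)$density_pct, lam = lacunarity(sk)$lambda_mean)
  })
  rd <- vapply(1:8, function(s) st(disc_like_mask(s)), numeric(2))
  rm <- vapply(1:8, function(s) st(macula_like_mask(s)), numeric(2))
  expect_lt(mean(rm["d", ]), mean(rd["d", ]))
  expect_lt(mean(rm["lam", ]), mean(rd["lam", ]))
  # skeleton coverage in the sparse vessel-like regime
  expect_true(all(rm["d", ] > 1 & rm["d", ] < 15))
  expect_true(all(rd["d", ] > 1 & rd["d", ] < 15))
})

test_that("cohorts write reproducible masks and a parseable manifest", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  man <- make_cohort(dir1, presets = cohort_presets(window = 384),
                     n_per_group = 2, seed = 5)
  expect_s3_class(man, "dataset_manifest")
  expect_equal(nrow(man), 6)
  expect_equal(sort(unique(man$group)), c("DR", "G", "H"))
  man2 <- make_cohort(dir2, presets = cohort_presets(window = 384),
                      n_per_group = 2, seed = 5)
  for (i in seq_len(nrow(man))) {
    expect_identical(readBin(man$mask[i], "raw", 2e6),
                     readBin(man2$mask[i], "raw", 2e6))
  }
  # single-group two-record cohort
  dir3 <- withr::local_tempdir()
  man3 <- make_cohort(dir3, presets = cohort_presets(window = 384)["H"],
                      n_per_group = 2, seed = 1)
  expect_equal(nrow(man3), 2)
  expect_error(make_cohort(withr::local_tempdir(), n_per_group = 1), ">= 2")
})

test_that("complexity rises with terminal-branch count on simulated trees", {
  sweep <- seq(0.15, 0.6, length.out = 10)
  res <- vapply(seq_along(sweep), function(i) {
    p <- tree_sim_params(seed = 100 + i, window = 320, branch_prob = sweep[i],
                         segment_length = c(30, 9), root_caliber = 12)
    sim <- simulate_tree(p)
    seg <- sim$tree$segments
    terminals <- sum(!(seg$child %in% seg$parent))
    c(terminals, box_count(skeletonize(sim$mask))$db)
  }, numeric(2))
  rho <- cor(res[1, ], res[2, ], method = "spearman")
  expect_gt(rho, 0)
})
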