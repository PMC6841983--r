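#' Deterministic fractal fixtures with known box-counting dimension
#'
#' Generates binary rasters whose limiting sets have exact, closed-form
#' box-counting dimensions, for validating the fractal estimator:
#' `line` (dimension 1), `filled_square` (2), `koch_curve`
#' (log 4 / log 3 ~ 1.2619) and `sierpinski_carpet` (log 8 / log 3 ~ 1.8928).
#' The carpet at recursion depth `order` keeps `8^order` cells, each a
#' filled `(side / 3^order)^2` block, so its foreground count is exactly
#' `8^order * (side / 3^order)^2`. The Koch curve is rasterized from its
#' order-`order` vector polyline with 1-px strokes; finite-order
#' rasterization biases its measured slope slightly more than the other
#' fixtures.
#'
#' @param kind One of `"line"`, `"filled_square"`, `"koch_curve"`,
#'   `"sierpinski_carpet"`.
#' @param order Recursion depth (ignored for line and filled square).
#' @param side Image side in px; the carpet requires a power of 3 with
#'   `side >= 3^order`.
#' @return A [binary_mask] of dimensions `side` x `side`.
#' @export
make_fractal <- function(kind = c("line", "filled_square", "koch_curve",
                                  "sierpinski_carpet"),
                         order = 0, side = 243) {
  kind <- match.arg(kind)
  side <- as.integer(side)
  if (side < 3 || order < 0) stop("invalid fractal spec", call. = FALSE)
  px <- switch(kind,
    line = {
      m <- matrix(FALSE, side, side)
      m[side %/% 2, ] <- TRUE
      m
    },
    filled_square = matrix(TRUE, side, side),
    sierpinski_carpet = {
      k <- round(log(side) / log(3))
      if (3^k != side || order > k) {
        stop("sierpinski_carpet needs side = 3^k with 3^order <= side",
             call. = FALSE)
      }
      idx <- seq_len(side) - 1
      keep <- matrix(TRUE, side, side)
      for (l in seq_len(order)) {
        cell <- (idx %/% (side / 3^l)) %% 3
        mid_r <- cell == 1
        keep <- keep & !outer(mid_r, mid_r, "&")
      }
      keep
    },
    koch_curve = {
      pts <- koch_polyline(order)
      # scale to the window with a small margin; bumps point up (smaller row)
      margin <- 4
      sc <- (side - 1 - 2 * margin)
      cx <- margin + pts[, 1] * sc
      cy <- (side - 1 - margin) - pts[, 2] * sc
      m <- matrix(FALSE, side, side)
      for (i in seq_len(nrow(pts) - 1)) {
        seg <- bresenham(round(cy[i]), round(cx[i]), round(cy[i + 1]), round(cx[i + 1]))
        m[cbind(seg$r + 1L, seg$c + 1L)] <- TRUE
      }
      m
    }
  )
  binary_mask(px, name = sprintf("%s_o%d_s%d", kind, order, side))
}

# Koch curve polyline on the unit base segment, order n: 4^n segments
koch_polyline <- function(order) {
  pts <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE)
  for (it in seq_len(order)) {
    out <- matrix(NA_real_, nrow = (nrow(pts) - 1) * 4 + 1, ncol = 2)
    k <- 1L
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      v <- (b - a) / 3
      p1 <- a + v
      p2 <- a + 2 * v
      # apex: p1 rotated +60 degrees about the segment direction
      apex <- p1 + c(v[1] * 0.5 - v[2] * sqrt(3) / 2,
                     v[1] * sqrt(3) / 2 + v[2] * 0.5)
      out[k, ] <- a
      out[k + 1, ] <- p1
      out[k + 2, ] <- apex
      out[k + 3, ] <- p2
      k <- k + 4L
    }
    out[k, ] <- pts[nrow(pts), ]
    pts <- out
  }
  pts
}

# integer line rasterization, 0-based endpoints, returns 0-based pixels
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  n <- max(dr, dc) + 1L
  list(r = round(seq(r0, r1, length.out = n)),
       c = round(seq(c0, c1, length.out = n)))
}

#' Parameters for the synthetic vascular tree simulator
#'
#' Defaults emulate the vessel scales seen by a fundus camera at roughly
#' 4.86 um/px: first-generation trunks of ~20 px (~97 um) caliber tapering
#' by a factor ~0.7 per branching generation over up to 5 generations, which
#' lands terminal branches near 4--5 px (~21 um). Trees grow segment by
#' segment: at each tip the vessel either bifurcates (probability
#' `branch_prob`, daughter-caliber ratio drawn uniformly from `asymmetry`)
#' or continues with slight caliber decay and direction jitter. A positive
#' `faz_radius` keeps a central disc free of vessels (foveal avascular
#' zone): segments are never grown into it and it is carved from the raster.
#'
#' @param root_caliber Trunk caliber in px (default 20).
#' @param taper Caliber factor per branching generation, in (0, 1)
#'   (default 0.7).
#' @param max_generations Cap on branching generations (default 5).
#' @param branch_prob Bifurcation probability per segment end (default 0.35).
#' @param asymmetry Length-2 range of the smaller/larger daughter caliber
#'   ratio (default `c(0.45, 0.95)`).
#' @param branch_angle_deg Mean and SD of the bifurcation deviation angle in
#'   degrees; draws are truncated to 10..80 (default `c(35, 10)`).
#' @param segment_length Mean and SD of segment length in px; draws are
#'   truncated to 8..3x mean (default `c(55, 18)`).
#' @param faz_radius Radius in px of the avascular disc at the window
#'   centre; 0 disables it.
#' @param min_caliber Visibility floor in px: tips whose caliber falls below
#'   it stop growing, emulating the fundus camera's failure to resolve
#'   vessels near capillary scale (default 2.5 px; sub-capillary vessels are
#'   absent from gold-standard segmentations).
#' @param window Square raster side in px (>= 64, default 1024).
#' @param seed Integer seed; the simulation is bit-reproducible given it.
#' @param root_pos Optional `c(row, col)` (0-based) of the root node;
#'   default is the mid-left edge.
#' @param root_dirs Initial trunk direction(s) in degrees (0 = rightward,
#'   positive = downward); one trunk per element.
#' @param prune_prob Per-step termination probability applied to tips of
#'   generation >= 3 in the half of the window containing the avascular
#'   centre; models terminal-branch pruning (default 0).
#' @param cont_decay Caliber factor per unbranched continuation step
#'   (default 0.985, a slow taper along a vessel's run; smaller values give
#'   short stubby vessels such as the radial peripapillary net).
#' @param orbit_strength Arcade curvature in 0..1: at each step,
#'   first- and second-generation vessels steer this fraction of the way
#'   toward the tangent of a circle about the window centre, bending the
#'   major trunks into arcs that enclose the macula-like centre the way
#'   temporal arcades do (0 = straight growth, default 0).
#' @param perifoveal_roots Number of fine perifoveal feeder systems placed
#'   on a ring around the window centre by [simulate_retina()] (0 = none;
#'   ignored by [simulate_tree()] itself). These emulate small perifoveal
#'   arterioles and venules arriving from all sides.
#' @param mesh_pitch Strand spacing in px of the quasi-regular perifoveal
#'   mesh laid around the window centre by [simulate_retina()] (0 = none).
#'   The perifoveal microvasculature forms a near-uniform mat with a
#'   characteristic spacing; a jittered wavy lattice reproduces its low
#'   lacunarity, which branching trees alone cannot.
#' @param mesh_radius_frac Outer radius of the mesh disc as a fraction of
#'   the window (default 0.22, spanning a macula-sized region of
#'   interest out to its corners).
#' @param mesh_dropout Fraction of mesh strand chunks randomly removed
#'   (default 0): models capillary drop-out / vascular pruning, which
#'   thins the mesh and makes it patchier.
#' @return A `tree_sim_params` list.
#' @export
tree_sim_params <- function(root_caliber = 20, taper = 0.7, max_generations = 5,
                            branch_prob = 0.35, asymmetry = c(0.45, 0.95),
                            branch_angle_deg = c(35, 10),
                            segment_length = c(55, 18),
                            faz_radius = 0, window = 1024, seed = 1,
                            root_pos = NULL, root_dirs = 0,
                            prune_prob = 0, min_caliber = 2.5,
                            cont_decay = 0.985, orbit_strength = 0,
                            perifoveal_roots = 0, mesh_pitch = 0,
                            mesh_radius_frac = 0.22, mesh_dropout = 0) {
  if (taper <= 0 || taper >= 1) stop("taper must be in (0, 1)", call. = FALSE)
  if (max_generations < 1) stop("max_generations must be >= 1", call. = FALSE)
  if (window < 64) stop("window must be >= 64 px", call. = FALSE)
  if (length(asymmetry) != 2 || asymmetry[1] > asymmetry[2] ||
      asymmetry[1] <= 0 || asymmetry[2] > 1) {
    stop("asymmetry must be an increasing range within (0, 1]", call. = FALSE)
  }
  if (branch_prob < 0 || branch_prob > 1 || prune_prob < 0 || prune_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (root_caliber <= 0 || faz_radius < 0 || min_caliber <= 0) {
    stop("invalid caliber/faz_radius", call. = FALSE)
  }
  structure(list(root_caliber = root_caliber, taper = taper,
                 max_generations = as.integer(max_generations),
                 branch_prob = branch_prob, asymmetry = asymmetry,
                 branch_angle_deg = branch_angle_deg,
                 segment_length = segment_length,
                 faz_radius = faz_radius, window = as.integer(window),
                 seed = as.integer(seed), root_pos = root_pos,
                 root_dirs = root_dirs, prune_prob = prune_prob,
                 min_caliber = min_caliber, cont_decay = cont_decay,
                 orbit_strength = orbit_strength,
                 perifoveal_roots = as.integer(perifoveal_roots),
                 mesh_pitch = mesh_pitch, mesh_radius_frac = mesh_radius_frac,
                 mesh_dropout = mesh_dropout),
            class = "tree_sim_params")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate a retinal-like vascular tree and its raster mask
#'
#' Grows a rooted vessel tree under [tree_sim_params()], recording ground
#' truth branching generations by the same diameter rules that
#' [assign_generations()] applies (generation increments at bifurcations:
#' the larger daughter continues the parent generation when the caliber
#' ratio is below 0.8, otherwise both daughters advance). Each segment is
#' rasterized as a stroke of its caliber width. The same seed always
#' reproduces bit-identical output.
#'
#' @param params A [tree_sim_params()].
#' @param raster If `FALSE`, skip rasterization and return only the tree
#'   (faster for tree-level studies).
#' @return A list with elements `tree` (a [vessel_tree] with ground-truth
#'   generations) and `mask` (a [binary_mask], or `NULL` if `raster = FALSE`).
#' @export
simulate_tree <- function(params, raster = TRUE) {
  stopifnot(inherits(params, "tree_sim_params"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(params$seed)
  W <- params$window
  ctr <- (W - 1) / 2
  root <- params$root_pos %||% c(W / 2, max(8, params$root_caliber))
  node_row <- root[1]; node_col <- root[2]
  seg_parent <- integer(); seg_child <- integer()
  seg_caliber <- numeric(); seg_gen <- integer()
  seg_from <- list(); seg_to <- list()
  max_segments <- 4000L
  # tip: node id, row, col, direction deg, caliber, generation
  tips <- lapply(params$root_dirs, function(d) {
    list(node = 1L, row = root[1], col = root[2], dir = d,
         caliber = params$root_caliber, gen = 1L)
  })
  # Clip a proposed segment to the window margin and the avascular zone.
  # Returns the endpoint plus whether the tip must terminate there, or NULL
  # when not even a 4-px stub fits. Clipping (rather than discarding the
  # step) guarantees every committed daughter materializes as a segment, so
  # the recorded generations stay recoverable from the realized tree.
  clip_step <- function(r0, c0, ang, len, cal) {
    v <- c(sin(ang), cos(ang))
    tmax <- len
    for (i in 1:2) {  # window bounds per axis, margin 1 px
      p0i <- if (i == 1) r0 else c0
      if (v[i] > 1e-9)  tmax <- min(tmax, ((W - 2) - p0i) / v[i])
      if (v[i] < -1e-9) tmax <- min(tmax, (1 - p0i) / v[i])
    }
    hard_stop <- tmax < len
    if (params$faz_radius > 0) {
      # first entry of the capsule centreline into the protected disc
      rad <- params$faz_radius + cal / 2 + 1
      w0 <- c(r0 - ctr, c0 - ctr)
      b <- sum(w0 * v); cc <- sum(w0^2) - rad^2
      disc <- b^2 - cc
      if (disc > 0) {
        t1 <- -b - sqrt(disc)
        if (t1 > 0 && t1 < tmax) {
          tmax <- t1
          hard_stop <- TRUE
        } else if (t1 <= 0 && -b + sqrt(disc) > 0) {
          return(NULL)  # already inside the protected zone
        }
      }
    }
    if (tmax < 4) return(NULL)
    list(r = r0 + tmax * v[1], c = c0 + tmax * v[2], stop = hard_stop)
  }
  # steer a direction toward the tangent of a circle about the window centre
  orbit_dir <- function(dir, row, col, gen) {
    if (params$orbit_strength <= 0 || gen > 2L) return(dir)
    vr <- row - ctr; vc <- col - ctr
    if (abs(vr) + abs(vc) < 1) return(dir)
    t1 <- atan2(vc, -vr) * 180 / pi   # the two tangent headings
    t2 <- atan2(-vc, vr) * 180 / pi
    d1 <- ((t1 - dir + 180) %% 360) - 180
    d2 <- ((t2 - dir + 180) %% 360) - 180
    dir + params$orbit_strength * (if (abs(d1) < abs(d2)) d1 else d2)
  }
  while (length(tips) && length(seg_parent) < max_segments) {
    tip <- tips[[1]]; tips <- tips[-1]
    if (tip$caliber < params$min_caliber) next
    if (params$prune_prob > 0 && tip$gen >= 3L && tip$col > 0.45 * W &&
        stats::runif(1) < params$prune_prob) next
    len <- rtrunc_norm(1, params$segment_length[1], params$segment_length[2],
                       8, 3 * params$segment_length[1])
    jitter <- stats::rnorm(1, 0, 7)
    new_dir <- orbit_dir(tip$dir + jitter, tip$row, tip$col, tip$gen)
    step <- clip_step(tip$row, tip$col, new_dir * pi / 180, len, tip$caliber)
    if (is.null(step)) next
    node_row <- c(node_row, step$r); node_col <- c(node_col, step$c)
    end_node <- length(node_row)
    seg_parent <- c(seg_parent, tip$node)
    seg_child <- c(seg_child, end_node)
    seg_caliber <- c(seg_caliber, tip$caliber)
    seg_gen <- c(seg_gen, tip$gen)
    seg_from[[length(seg_from) + 1L]] <- c(tip$row, tip$col)
    seg_to[[length(seg_to) + 1L]] <- c(step$r, step$c)
    if (step$stop) next
    can_branch <- tip$gen < params$max_generations
    r <- if (can_branch) stats::runif(1, params$asymmetry[1], params$asymmetry[2]) else 1
    if (can_branch && stats::runif(1) < params$branch_prob &&
        tip$caliber * params$taper * r >= params$min_caliber) {
      delta <- rtrunc_norm(1, params$branch_angle_deg[1],
                           params$branch_angle_deg[2], 10, 80)
      side <- sample(c(-1, 1), 1)
      if (r < 0.8) {
        # asymmetric: larger daughter continues the parent generation
        big_cal <- tip$caliber * 0.95
        big_gen <- tip$gen
        big_dir <- new_dir + side * delta * 0.25
      } else {
        big_cal <- tip$caliber * params$taper
        big_gen <- tip$gen + 1L
        big_dir <- new_dir + side * delta * 0.6
      }
      small_cal <- big_cal * r
      tips[[length(tips) + 1L]] <- list(node = end_node, row = step$r, col = step$c,
                                        dir = big_dir, caliber = big_cal,
                                        gen = big_gen)
      tips[[length(tips) + 1L]] <- list(node = end_node, row = step$r, col = step$c,
                                        dir = new_dir - side * delta,
                                        caliber = small_cal, gen = tip$gen + 1L)
    } else {
      tips[[length(tips) + 1L]] <- list(node = end_node, row = step$r, col = step$c,
                                        dir = new_dir,
                                        caliber = tip$caliber * params$cont_decay,
                                        gen = tip$gen)
    }
  }
  nodes <- data.frame(id = seq_along(node_row), row = node_row, col = node_col)
  segments <- data.frame(parent = seg_parent, child = seg_child,
                         caliber = seg_caliber, generation = seg_gen)
  tree <- vessel_tree(nodes, segments)
  mask <- NULL
  if (raster) {
    px <- matrix(FALSE, W, W)
    for (i in seq_along(seg_from)) {
      px <- stroke_segment(px, seg_from[[i]], seg_to[[i]], seg_caliber[i])
    }
    if (params$faz_radius > 0) {
      idx <- seq_len(W) - 1
      d2 <- outer((idx - ctr)^2, (idx - ctr)^2, "+")
      px[d2 <= params$faz_radius^2] <- FALSE
    }
    mask <- binary_mask(px, name = sprintf("tree_seed%d", params$seed))
  }
  list(tree = tree, mask = mask)
}

# draw a capsule of width `caliber` between p0 and p1 (0-based coords)
stroke_segment <- function(px, p0, p1, caliber) {
  W <- nrow(px)
  half <- caliber / 2
  r0 <- max(1, floor(min(p0[1], p1[1]) - half))
  r1 <- min(W, ceiling(max(p0[1], p1[1]) + half) + 1)
  c0 <- max(1, floor(min(p0[2], p1[2]) - half))
  c1 <- min(ncol(px), ceiling(max(p0[2], p1[2]) + half) + 1)
  if (r1 < r0 || c1 < c0) return(px)  # stroke entirely outside the window
  rr <- r0:r1 - 1
  cc <- c0:c1 - 1
  v <- c(p1[1] - p0[1], p1[2] - p0[2])
  len2 <- sum(v^2)
  gr <- matrix(rr, length(rr), length(cc))
  gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  t <- if (len2 == 0) matrix(0, length(rr), length(cc)) else
    pmin(pmax(((gr - p0[1]) * v[1] + (gc - p0[2]) * v[2]) / len2, 0), 1)
  d2 <- (gr - (p0[1] + t * v[1]))^2 + (gc - (p0[2] + t * v[2]))^2
  hit <- d2 <= half^2
  px[r0:r1, c0:c1] <- px[r0:r1, c0:c1] | hit
  px
}

#' Simulate a full retina-like mask
#'
#' Composes up to three vessel systems into one fundus-like mask: the main
#' arcade tree grown under `params` from the optic-disc root; a radial
#' peripapillary net — short, stubby spokes bundled around the disc that
#' reproduce the dense small-vessel halo a fundus camera sees there; and,
#' when `params$perifoveal_roots > 0`, a ring of fine perifoveal feeders
#' around the window centre whose twigs mesh evenly up to the avascular
#' zone. The combined mask is the union of the rasters; the returned tree
#' is the arcade system's.
#'
#' @param params [tree_sim_params()] for the arcade system; the accessory
#'   systems derive their window, geometry, avascular zone and seeds from
#'   it.
#' @param tuft Set `FALSE` to omit the peripapillary net.
#' @return List with `mask` (a [binary_mask]) and `tree` (the arcade
#'   [vessel_tree] with ground-truth generations).
#' @export
simulate_retina <- function(params, tuft = TRUE) {
  sim <- simulate_tree(params)
  if (tuft) {
    tp <- params
    tp$root_dirs <- c(35, 55, -35, -55, 145, 165, -145, -165)
    tp$root_caliber <- min(2.5, params$root_caliber / 2)
    tp$max_generations <- 2L
    tp$branch_prob <- 0.5
    tp$segment_length <- c(30, 10)
    tp$min_caliber <- 0.65 * tp$root_caliber
    tp$cont_decay <- 0.93
    tp$prune_prob <- 0
    tp$orbit_strength <- 0
    tp$seed <- params$seed + 37L
    sim$mask$pixels <- sim$mask$pixels | simulate_tree(tp)$mask$pixels
  }
  if (params$perifoveal_roots > 0) {
    W <- params$window
    ring <- 0.146 * W
    for (k in seq_len(params$perifoveal_roots)) {
      ang <- 2 * pi * k / params$perifoveal_roots
      fp <- params
      fp$root_pos <- c((W - 1) / 2 + ring * sin(ang),
                       (W - 1) / 2 + ring * cos(ang))
      fp$root_dirs <- (ang * 180 / pi + 180) + c(-35, 35)  # aimed inward
      fp$root_caliber <- min(2.2, params$root_caliber / 2.5)
      fp$max_generations <- 2L
      fp$branch_prob <- 0.3
      fp$segment_length <- c(20, 7)
      fp$min_caliber <- min(1.2, params$min_caliber)
      fp$cont_decay <- 0.9
      fp$prune_prob <- 0
      fp$orbit_strength <- 0
      fp$perifoveal_roots <- 0L
      fp$seed <- params$seed + 101L + k
      sim$mask$pixels <- sim$mask$pixels | simulate_tree(fp)$mask$pixels
    }
  }
  if (params$mesh_pitch > 0) {
    W <- params$window
    sim$mask$pixels <- sim$mask$pixels |
      lattice_mesh(W, radius = params$mesh_radius_frac * W,
                   faz_radius = params$faz_radius, pitch = params$mesh_pitch,
                   caliber = max(1.2, min(1.8, params$min_caliber)),
                   dropout = params$mesh_dropout, seed = params$seed + 71L)
  }
  list(mask = sim$mask, tree = sim$tree)
}

# Quasi-regular wavy lattice of fine strands inside a disc about the window
# centre, excluding the avascular core. Lines in both orientations at the
# given pitch, with smooth sinusoidal waviness and random phases; `dropout`
# removes random chunks of strand, thinning the mesh and making it patchy.
lattice_mesh <- function(window, radius, faz_radius, pitch, caliber,
                         dropout = 0, seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  ctr <- (window - 1) / 2
  px <- matrix(FALSE, window, window)
  lo <- max(1, floor(ctr - radius)); hi <- min(window - 2, ceiling(ctr + radius))
  step <- max(8, pitch %/% 3)
  draw_line <- function(fixed, horizontal) {
    amp <- stats::runif(1, 0.12, 0.3) * pitch
    wl <- stats::runif(1, 2.5, 4) * pitch
    phase <- stats::runif(1, 0, 2 * pi)
    xs <- seq(lo, hi, by = step)
    ys <- fixed + amp * sin(2 * pi * xs / wl + phase)
    for (i in seq_len(length(xs) - 1)) {
      if (dropout > 0 && stats::runif(1) < dropout) next
      p0 <- if (horizontal) c(ys[i], xs[i]) else c(xs[i], ys[i])
      p1 <- if (horizontal) c(ys[i + 1], xs[i + 1]) else c(xs[i + 1], ys[i + 1])
      px <<- stroke_segment(px, p0, p1, caliber)
    }
  }
  offsets <- seq(ctr - radius + pitch / 2, ctr + radius, by = pitch)
  for (f in offsets) {
    draw_line(f + stats::runif(1, -0.2, 0.2) * pitch, horizontal = TRUE)
    draw_line(f + stats::runif(1, -0.2, 0.2) * pitch, horizontal = FALSE)
  }
  idx <- seq_len(window) - 1
  d2 <- outer((idx - ctr)^2, (idx - ctr)^2, "+")
  px[d2 > radius^2] <- FALSE
  if (faz_radius > 0) px[d2 <= faz_radius^2] <- FALSE
  px
}

#' Region-archetype preset masks
#'
#' Single-window stand-ins for the two study regions of a fundus image,
#' used to validate direction-of-effect expectations without a full
#' cohort. `disc_like_mask()` grows one radially branching tree from the
#' window centre with large trunk calibers and no avascular zone — the
#' optic-disc pattern, whose trunk corridors and empty sectors make it
#' heterogeneous (high lacunarity). `macula_like_mask()` lays a
#' quasi-regular fine mesh with a central avascular zone plus a few fine
#' feeder trees from the border — the perifoveal pattern: slightly lower
#' skeleton density but far more even, hence lower lacunarity.
#'
#' @param seed Integer seed.
#' @param window Window side in px (default 512, standing for a 1000-px
#'   region of interest).
#' @return A [binary_mask].
#' @export
disc_like_mask <- function(seed, window = 512) {
  p <- tree_sim_params(seed = seed, window = window,
                       root_pos = c(window / 2, window / 2),
                       root_dirs = seq(20, 340, length.out = 7),
                       root_caliber = 0.0203 * window, min_caliber = 0.005 * window,
                       branch_prob = 0.9, branch_angle_deg = c(14, 5),
                       segment_length = c(round(0.055 * window), round(0.018 * window)),
                       faz_radius = 0, cont_decay = 0.96)
  m <- simulate_tree(p)$mask
  # dense short-range knot where vessels crowd into the disc
  kp <- tree_sim_params(seed = seed + 19L, window = window,
                        root_pos = c(window / 2, window / 2),
                        root_dirs = seq(5, 345, by = 20),
                        root_caliber = 0.008 * window, min_caliber = 0.004 * window,
                        branch_prob = 0.5, max_generations = 2,
                        segment_length = c(round(0.03 * window), round(0.01 * window)),
                        faz_radius = 0, cont_decay = 0.8)
  m$pixels <- m$pixels | simulate_tree(kp)$mask$pixels
  m$name <- sprintf("disc_like_seed%d", seed)
  m
}

#' @rdname disc_like_mask
#' @export
macula_like_mask <- function(seed, window = 512) {
  faz <- round(0.055 * window)
  px <- lattice_mesh(window, radius = 0.71 * window, faz_radius = faz,
                     pitch = round(0.128 * window), caliber = 1.6,
                     dropout = 0, seed = seed)
  # a few fine feeders crossing in from the border
  for (k in 1:4) {
    ang <- 2 * pi * k / 4 + 0.3
    p <- tree_sim_params(seed = seed * 200L + k, window = window,
          root_pos = c((window - 1) / 2 + 0.47 * window * sin(ang),
                       (window - 1) / 2 + 0.47 * window * cos(ang)),
          root_dirs = ang * 180 / pi + 180 + c(-20, 20),
          root_caliber = 3, min_caliber = 1.1, branch_prob = 0.3,
          max_generations = 2, faz_radius = faz, cont_decay = 0.93,
          segment_length = c(round(0.05 * window), round(0.016 * window)))
    px <- px | simulate_tree(p)$mask$pixels
  }
  binary_mask(px, sprintf("macula_like_seed%d", seed))
}

#' Group presets for synthetic cohorts
#'
#' Returns per-group [tree_sim_params()] emulating a healthy (`H`),
#' glaucoma (`G`) and diabetic-retinopathy (`DR`) retina on a square
#' window: an optic-disc-like root on the left third sends four
#' first-generation trunks across the field, and the macula-like centre of
#' the window carries a foveal avascular zone. The `DR` preset prunes
#' macula-side terminal branches (vascular pruning) and enlarges the
#' avascular zone; the `G` preset mildly reduces branching.
#'
#' @param window Raster side in px (default 1024).
#' @return Named list of `tree_sim_params` for groups `H`, `G`, `DR`.
#' @export
cohort_presets <- function(window = 1024) {
  od <- c(window / 2, round(0.1875 * window))
  # bundled arcades skirting the horizontal corridor toward the macula
  dirs <- c(55, 63, 71, -55, -63, -71, 140, 152, -140, -152)
  # calibers and the avascular radius scale with the window so that a
  # 1024-px window stands for a ~3500-px fundus: trunks ~99 um, visibility
  # floor ~21 um, FAZ radius ~270 um
  sc <- window / 3504
  base <- function(branch_prob = 0.55, faz_radius = round(55 * sc),
                   mesh_dropout = 0, ...) {
    tree_sim_params(window = window, root_pos = od, root_dirs = dirs,
                    root_caliber = 20.3 * sc, min_caliber = max(1, 4.4 * sc),
                    faz_radius = faz_radius, branch_prob = branch_prob,
                    perifoveal_roots = 4, mesh_pitch = round(0.0585 * window),
                    mesh_dropout = mesh_dropout,
                    segment_length = c(round(0.054 * window),
                                       round(0.018 * window)), ...)
  }
  list(H = base(),
       G = base(branch_prob = 0.52, mesh_dropout = 0.1),
       DR = base(branch_prob = 0.5, prune_prob = 0.3, mesh_dropout = 0.5,
                 faz_radius = round(83 * sc)))
}

#' Generate a synthetic cohort on disk
#'
#' Writes `n_per_group` mask PNGs per group plus a `manifest.csv` in the
#' [read_manifest()] dialect; optic-disc centres sit at each preset's root
#' and macula centres at the window centre (where the avascular zone is).
#' The whole cohort is reproducible from a single integer seed (per-image
#' seeds are derived from it).
#'
#' @param dir Output directory (created if needed).
#' @param presets Named list of per-group [tree_sim_params()]; defaults to
#'   [cohort_presets()].
#' @param n_per_group Images per group (>= 2 for downstream statistics).
#' @param seed Integer master seed.
#' @return The manifest as a `dataset_manifest` (invisibly also written to
#'   `dir/manifest.csv`).
#' @export
make_cohort <- function(dir, presets = cohort_presets(), n_per_group = 15,
                        seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  rows <- list()
  gi <- 0L
  for (g in names(presets)) {
    gi <- gi + 1L
    p <- presets[[g]]
    for (i in seq_len(n_per_group)) {
      p$seed <- as.integer((seed * 1000L + gi * 100L + i) %% .Machine$integer.max)
      sim <- simulate_retina(p)
      fn <- file.path(dir, sprintf("%s%02d.png", g, i))
      write_mask(sim$mask, fn)
      od <- p$root_pos %||% c(p$window / 2, max(8, p$root_caliber))
      rows[[length(rows) + 1L]] <- data.frame(
        image = fn, mask = fn, group = g,
        od_x = od[2], od_y = od[1],
        mac_x = (p$window - 1) / 2, mac_y = (p$window - 1) / 2)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, file.path(dir, "manifest.csv"), row.names = FALSE)
  read_manifest(file.path(dir, "manifest.csv"), groups = names(presets),
                roi_size = round(0.3125 * presets[[1]]$window))
}
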