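test_that("interpolation reproduces constant and linear fields", {
  mont <- standard_montage()
  vals <- rep(0.4, 32)
  topo <- interpolate_topo(vals, mont, res = 64)
  expect_true(all(abs(topo$grid[topo$mask] - 0.4) < 1e-9))
  expect_true(all(is.na(topo$grid[!topo$mask])))

  ## linear field a*x + b*y reproduced at interior nodes of the hull
  a <- 0.3; b <- -0.2
  lin <- a * mont$positions[, "x"] + b * mont$positions[, "y"] + 0.5
  topo2 <- interpolate_topo(lin, mont, res = 64)
  gx <- seq(-1, 1, length.out = 64)
  gy <- seq(1, -1, length.out = 64)
  ## probe nodes well inside the electrode hull (radius < 0.55)
  for (i in seq(8, 56, by = 8)) {
    for (j in seq(8, 56, by = 8)) {
      if (gx[j]^2 + gy[i]^2 < 0.3) {
        expect_equal(topo2$grid[i, j], a * gx[j] + b * gy[i] + 0.5,
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("interpolation is exact at electrode sites", {
  mont <- standard_montage()
  set.seed(7)
  vals <- runif(32)
  ## exact electrode coordinates reproduce their values to rounding
  tris <- saetm:::.delaunay(mont$positions)
  W <- saetm:::.interp_weights(mont$positions, mont$positions, tris)
  expect_lt(max(abs(as.numeric(W %*% vals) - vals)), 1e-9)
  res <- 257   # odd: electrode coordinates land close to grid nodes
  topo <- interpolate_topo(vals, mont, res = res)
  gx <- seq(-1, 1, length.out = res)
  gy <- seq(1, -1, length.out = res)
  for (ch in c("Cz", "T7", "Oz", "F3")) {
    p <- mont$positions[ch, ]
    i <- which.min(abs(gy - p["y"])); j <- which.min(abs(gx - p["x"]))
    ## Cz/T7/Oz sit exactly on grid nodes of the odd grid
    v <- unname(vals[match(ch, canonical_channels())])
    if (max(abs(c(gx[j] - p["x"], gy[i] - p["y"]))) < 1e-12) {
      expect_lt(abs(topo$grid[i, j] - v), 1e-6)    # coincident node: exact
    } else {
      expect_lt(abs(topo$grid[i, j] - v), 0.05)    # nearest node: close
    }
  }
})

test_that("mirrored inputs give a mirrored map", {
  mont <- standard_montage()
  set.seed(9)
  vals <- stats::setNames(runif(32), canonical_channels())
  pairs <- saetm:::.mirror_pairs()
  swapped <- vals
  swapped[pairs$left] <- vals[pairs$right]
  swapped[pairs$right] <- vals[pairs$left]
  t1 <- interpolate_topo(vals, mont, res = 64)
  t2 <- interpolate_topo(swapped, mont, res = 64)
  ## mirror about the y axis = reverse columns
  expect_equal(t2$grid, t1$grid[, 64:1], tolerance = 1e-6)
})

test_that("interpolation rejects non-finite values", {
  vals <- rep(0.5, 32); vals[3] <- NaN
  expect_error(interpolate_topo(vals), "finite")
  expect_error(interpolate_topo(rep(0.5, 31)), "per electrode")
})

test_that("rendering is deterministic with correct colour endpoints", {
  mont <- standard_montage()
  set.seed(11)
  vals <- runif(32)
  topo <- interpolate_topo(vals, mont, res = 64)
  p1 <- file.path(tempdir(), "m1.png"); p2 <- file.path(tempdir(), "m2.png")
  render_png(topo, p1); render_png(topo, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  ## constant map -> a single hue inside the head (away from the outline)
  tc <- interpolate_topo(rep(0.5, 32), mont, res = 64)
  pc <- file.path(tempdir(), "mc.png")
  render_png(tc, pc)
  img <- png::readPNG(pc)
  centre <- img[25:40, 25:40, ]
  expect_lt(max(abs(sweep(centre, 3, centre[1, 1, ]))), 1e-6)

  ## extreme values map to the colormap endpoints at their electrodes
  ve <- rep(0.5, 32)
  ve[match("T7", canonical_channels())] <- 0
  ve[match("T8", canonical_channels())] <- 1
  te <- interpolate_topo(ve, mont, res = 129)
  pe <- file.path(tempdir(), "me.png")
  render_png(te, pe)
  img <- png::readPNG(pe)
  gx <- seq(-1, 1, length.out = 129); gy <- seq(1, -1, length.out = 129)
  i7 <- which.min(abs(gy - 0)); j7 <- which.min(abs(gx + 0.8))
  j8 <- which.min(abs(gx - 0.8))
  expect_equal(as.numeric(img[i7, j7, 1:3]), c(0, 0, 0.5), tolerance = 0.05)
  expect_equal(as.numeric(img[i7, j8, 1:3]), c(0.5, 0, 0), tolerance = 0.05)
})

test_that("rendered electrode colours respect the value ordering", {
  mont <- standard_montage()
  set.seed(13)
  vals <- runif(32)
  topo <- interpolate_topo(vals, mont, res = 129)
  path <- file.path(tempdir(), "ord.png")
  render_png(topo, path)
  img <- png::readPNG(path)
  gx <- seq(-1, 1, length.out = 129); gy <- seq(1, -1, length.out = 129)
  ## recover each electrode pixel's colormap parameter by nearest colour
  ref_t <- seq(0, 1, length.out = 512)
  ref <- saetm:::.jet(ref_t)
  t_hat <- vapply(seq_len(32), function(ch) {
    p <- mont$positions[ch, ]
    i <- which.min(abs(gy - p["y"])); j <- which.min(abs(gx - p["x"]))
    col <- as.numeric(img[i, j, 1:3])
    ref_t[which.min(colSums((t(ref) - col)^2))]
  }, 0)
  ## larger channel value never renders as a colder (smaller-t) colour
  ord <- order(vals)
  expect_true(all(diff(t_hat[ord]) >= -0.05))
})

test_that("single-feature maps average windows and validate the index", {
  zero <- structure(list(tensor = array(0, c(5, 32, 10),
                                        dimnames = list(NULL,
                                                        canonical_channels(),
                                                        feature_names())),
                         label = NULL, meta = list()),
                    class = "feature_tensor")
  tm <- single_feature_map(zero, 2)
  expect_true(all(tm$grid[tm$mask] == 0))
  expect_error(single_feature_map(zero, 11), "1..10")
  expect_error(single_feature_map(zero, "not_a_feature"), "1..10")
  ## named lookup matches positional lookup
  set.seed(3)
  rnd <- zero
  rnd$tensor[] <- runif(length(rnd$tensor))
  m1 <- single_feature_map(rnd, 2)
  m2 <- single_feature_map(rnd, "power_alpha")
  expect_identical(m1$grid, m2$grid)
})

test_that("grid down-sampling preserves block means", {
  mont <- standard_montage()
  topo <- interpolate_topo(rep(0.25, 32), mont, res = 128)
  g <- map_grid_matrix(topo, 64)
  expect_identical(dim(g), c(64L, 64L))
  ## interior blocks keep the constant value
  expect_equal(g[32, 32], 0.25, tolerance = 1e-9)
  expect_error(map_grid_matrix(topo, 60), "%%")
})
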