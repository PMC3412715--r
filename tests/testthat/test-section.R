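test_that("axis-aligned cut reproduces a gradient plane exactly", {
  g <- make_gradient_volume(c(10, 10, 10))
  sec <- cut_section(g, view_spec(dist = 5))
  expect_equal(dim(sec$pixels), c(10, 10))
  want <- outer(0:9 * 10, 0:9, `+`) + 500   # [l, k] = k + 10 l + 100*5
  expect_equal(sec$pixels, want)
  expect_true(all(sec$inside))
})

test_that("oblique sphere cuts through the centre have the analytic area", {
  r <- 20
  sph <- make_sphere_phantom(c(45, 45, 45), centre = c(22, 22, 22), radius = r)
  set.seed(31)
  errs <- vapply(1:5, function(i) {
    vw <- view_spec(fixed = c(22, 22, 22),
                    pitch = stats::runif(1, -90, 90),
                    yaw = stats::runif(1, -180, 180), dist = 0)
    msk <- cut_domain_section(sph$domain, vw,
                              frame = section_frame(bounding_box(sph),
                                                    build_transform(vw)))
    abs(sum(msk) - pi * r^2) / (pi * r^2)
  }, numeric(1))
  # per-view digitisation error of the r=20 digital ball stays within a few
  # per cent and shows no systematic bias across orientations
  expect_lt(max(errs), 0.04)
  expect_lt(mean(errs), 0.02)
})

test_that("arbitrary views match the per-pixel inverse-map oracle bit-exactly", {
  g <- make_gradient_volume(c(12, 12, 12))
  set.seed(32)
  for (i in 1:8) {
    vw <- resolve_mode(random_view())
    t <- build_transform(vw)
    frame <- section_frame(bounding_box(g), t)
    w <- min(frame$width, 24); h <- min(frame$height, 24)
    sec <- cut_section(g, vw, region = c(0, 0, w, h))
    ora <- oracle_cut_section(g, vw, frame, w, h)
    expect_identical(sec$pixels, ora$pixels)
    expect_identical(sec$inside, ora$inside)
  }
})

test_that("domain sections OR together like their union (homomorphism)", {
  comp <- make_compound_phantom(c(40, 40, 40), n_members = 2, overlap = 0.5)
  d0 <- member(comp, 0)$domain
  d1 <- member(comp, 1)$domain
  u <- domain_binary_op(d0, d1, "union")
  c0 <- bounding_box(member(comp, 0)); c1 <- bounding_box(member(comp, 1))
  lens <- floor((floor((c0[1:3] + c0[4:6]) / 2) +
                   floor((c1[1:3] + c1[4:6]) / 2)) / 2)
  vw <- view_spec(pitch = 30, yaw = 20, fixed = unname(lens))
  frame <- section_frame(unname(bounding_box(comp)), build_transform(vw))
  m0 <- cut_domain_section(d0, vw, frame = frame)
  m1 <- cut_domain_section(d1, vw, frame = frame)
  mu <- cut_domain_section(u, vw, frame = frame)
  expect_identical(m0 | m1, mu)
  expect_gt(sum(m0 & m1), 0)   # the overlap is actually exercised
})

test_that("empty and full domains cut to all-false / footprint masks", {
  vw <- view_spec(dist = 2)
  e <- cut_domain_section(empty_domain(), vw, region = c(0, 0, 8, 8))
  expect_false(any(e))
  box <- domain_from_mask(array(TRUE, c(5, 6, 7)))
  m <- cut_domain_section(box, vw)
  expect_equal(dim(m), c(6, 5))
  expect_true(all(m))
})

test_that("distance scrolling shifts a gradient section by 100 per plane", {
  g <- make_gradient_volume(c(10, 10, 10))
  s3 <- cut_section(g, view_spec(dist = 3))
  s7 <- cut_section(g, view_spec(dist = 7))
  expect_true(all(s7$pixels - s3$pixels == 400))
})

test_that("scale 2 at level 1 reproduces scale 1 at level 0", {
  # dist is in scaled view units: the same object plane sits at 2x the
  # distance under scale 2, so anchor the plane with the fixed point instead
  g <- make_gradient_volume(c(10, 10, 10))
  a <- cut_section(g, view_spec(fixed = c(0, 0, 4)), level = 0)
  b <- cut_section(g, view_spec(fixed = c(0, 0, 4), scale = 2), level = 1)
  expect_identical(b$pixels, a$pixels)
})

test_that("levels sample sparsely and downscale box-filters", {
  g <- make_gradient_volume(c(64, 64, 8))
  s0 <- cut_section(g, view_spec(dist = 3), level = 0)
  s1 <- cut_section(g, view_spec(dist = 3), level = 1)
  expect_equal(dim(s1$pixels), c(32, 32))
  expect_identical(s1$pixels, s0$pixels[seq(1, 64, 2), seq(1, 64, 2)])

  # constant image: every pyramid level is the same constant
  con <- voxvol_from_array(array(9, c(16, 16, 4)), kind = "u8")
  cs <- cut_section(con, view_spec(dist = 1))
  expect_true(all(downscale(cs, 1)$pixels == 9))
  expect_true(all(downscale(cs, 2)$pixels == 9))
  expect_equal(dim(downscale(cs, 1)$pixels), c(8, 8))

  # linear ramp: the box filter returns the window-centre value, so it sits
  # ((2^l - 1)/2) * (1 + 10) grey above the sparse top-left sample
  d2 <- downscale(s0, 2)
  direct2 <- cut_section(g, view_spec(dist = 3), level = 2)
  diff <- d2$pixels - direct2$pixels
  expect_true(all(diff %in% c(16, 17)))   # 16.5 quantised either way
})

test_that("tiling mosaics are bit-exact against the one-shot cut", {
  g <- make_gradient_volume(c(40, 30, 6))
  vw <- view_spec(pitch = 15, yaw = -25, dist = 1)
  t <- build_transform(vw)
  frame <- section_frame(bounding_box(g), t)
  for (level in 0:1) {
    full <- cut_section(g, vw, level = level)
    step <- 2^level
    lw <- ceiling(frame$width / step); lh <- ceiling(frame$height / step)
    mosaic <- matrix(NA_real_, lh, lw)
    ts <- c(16L, 16L)
    grid <- tile_grid(c(lw, lh), ts)
    for (idx in seq_len(grid$count) - 1L) {
      reg <- tile_region(frame, level, idx, ts)
      tile <- cut_section(g, vw, region = reg, level = level, frame = frame)
      x0 <- reg[1] / step; y0 <- reg[2] / step
      mosaic[y0 + seq_len(nrow(tile$pixels)),
             x0 + seq_len(ncol(tile$pixels))] <- tile$pixels
    }
    expect_identical(mosaic, full$pixels)
  }
})

test_that("rgba sectioning commutes with per-channel sectioning", {
  rgb <- make_rgb_phantom(c(12, 12, 6))
  vw <- view_spec(pitch = 20, yaw = 35, dist = 1, fixed = c(6, 6, 3))
  sec <- cut_section(rgb, vw)
  for (ch in 1:4) {
    mono <- voxvol(rgb$domain, rgb$values[, , , ch], "u8", rgb$voxel_size)
    schan <- cut_section(mono, vw)
    expect_identical(sec$pixels[, , ch][sec$inside], schan$pixels[schan$inside])
  }
  # blue channel of an axis-aligned cut is constant = plane index
  s2 <- cut_section(rgb, view_spec(dist = 2))
  expect_true(all(s2$pixels[, , 3] == 2))
})

test_that("trilinear sampling is exact on a linear field and at voxel centres", {
  g <- make_gradient_volume(c(12, 12, 12))
  vw <- view_spec(dist = 5)
  nn <- cut_section(g, vw)
  tri <- cut_section(g, vw, interp = "trilinear")
  expect_equal(tri$pixels, nn$pixels)   # on-lattice: identical
  # off-lattice: a half-voxel shifted plane averages the two nearest planes
  vh <- view_spec(dist = 5.5)
  tri2 <- cut_section(g, vh, interp = "trilinear",
                      region = c(2, 2, 6, 6))
  nn2 <- cut_section(g, vh, region = c(2, 2, 6, 6))
  expect_true(all((tri2$pixels - nn2$pixels) %in% c(-50, 50)))
  expect_error(cut_section(make_rgb_phantom(c(4, 4, 4)), vw,
                           interp = "trilinear"), "grey")
})
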