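# Independent oracles used across the suite. Everything here is deliberately
# naive (dense grids, per-pixel loops, textbook formulas) and shares no code
# with the implementation paths it checks.

# Rodrigues rotation of vectors about a unit axis (right-handed, CCW)
rodrigues <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# frame rotation for (pitch, yaw, roll) built from axis-angle pieces: a frame
# rotation is the transpose of the corresponding vector rotation
oracle_rotation <- function(pitch, yaw, roll) {
  t(rodrigues(c(0, 0, 1), roll)) %*%
    t(rodrigues(c(0, 1, 0), pitch)) %*%
    t(rodrigues(c(0, 0, 1), yaw))
}

# dense-mask oracle for binary domain ops over the union bounding box
oracle_binary_op <- function(a, b, op) {
  bb <- c(pmin(bounding_box(a)[1:3], bounding_box(b)[1:3]),
          pmax(bounding_box(a)[4:6], bounding_box(b)[4:6]))
  grid <- expand.grid(k = bb[1]:bb[4], l = bb[2]:bb[5], p = bb[3]:bb[6])
  ina <- domain_contains(a, grid$k, grid$l, grid$p)
  inb <- domain_contains(b, grid$k, grid$l, grid$p)
  want <- switch(op, union = ina | inb, intersect = ina & inb,
                 difference = ina & !inb)
  dims <- c(bb[4] - bb[1] + 1, bb[5] - bb[2] + 1, bb[6] - bb[3] + 1)
  domain_from_mask(array(want, dims), origin = bb[1:3])
}

# per-pixel section oracle: its own rotation, its own inverse map, its own
# nearest-voxel rounding, dense-array value lookup. Slow by design.
oracle_cut_section <- function(vol, view, frame, w, h, level = 0) {
  stopifnot(view$mode == "absolute")
  R <- oracle_rotation(view$pitch, view$yaw, view$roll)
  dm <- domain_to_mask(vol$domain)
  dims <- dim(dm$mask)
  vals <- if (!is.null(vol$values)) vol$values else NULL
  out <- matrix(vol$background[1], h, w)
  inside <- matrix(FALSE, h, w)
  step <- 2^level
  for (j in seq_len(h)) {
    for (i in seq_len(w)) {
      vp <- c((i - 1) * step + frame$x_off, (j - 1) * step + frame$y_off,
              view$dist)
      obj <- as.numeric(t(R) %*% (vp / view$scale)) + view$fixed
      vox <- floor(obj + 0.5)
      ii <- vox - dm$origin + 1
      if (all(ii >= 1) && all(ii <= dims) && dm$mask[ii[1], ii[2], ii[3]]) {
        inside[j, i] <- TRUE
        if (!is.null(vals)) out[j, i] <- vals[ii[1], ii[2], ii[3]]
      }
    }
  }
  list(pixels = out, inside = inside)
}

# scalar source-over in premultiplied form, one pixel at a time
oracle_over <- function(layers_rgba) {
  acc <- c(0, 0, 0, 0)
  for (lay in layers_rgba) {
    a <- lay[4] / 255
    src <- c(lay[1:3] / 255 * a, a)
    acc <- src + acc * (1 - a)
  }
  rgb <- if (acc[4] > 0) acc[1:3] / acc[4] else c(0, 0, 0)
  c(floor(pmin(pmax(rgb, 0), 1) * 255 + 0.5),
    floor(pmin(pmax(acc[4], 0), 1) * 255 + 0.5))
}

random_view <- function(allow_modes = "absolute") {
  mode <- sample(allow_modes, 1)
  view_spec(fixed = stats::runif(3, -5, 15),
            pitch = stats::runif(1, -180, 180),
            yaw = stats::runif(1, -180, 180),
            roll = stats::runif(1, -180, 180),
            dist = stats::runif(1, -4, 4),
            scale = stats::runif(1, 0.5, 2.5),
            mode = mode,
            up = if (mode == "up_is_up") {
              u <- stats::rnorm(3); u / sqrt(sum(u^2))
            } else c(0, 0, -1),
            fixed2 = if (mode == "fixed_line") stats::runif(3, -5, 15),
            line_angle = stats::runif(1, -180, 180))
}

expect_same_domain <- function(a, b) {
  expect_equal(is_empty_domain(a), is_empty_domain(b))
  if (!is_empty_domain(a)) {
    expect_equal(unname(a$ivs), unname(b$ivs))
    expect_equal(a$bbox, b$bbox)
  }
}
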