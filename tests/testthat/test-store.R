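test_that("block shapes must align with filesystem blocks", {
  g <- make_gradient_volume(c(10, 10, 10), kind = "u8")
  p <- tempfile(fileext = ".blk")
  expect_error(write_store(g, p, block_shape = c(10, 10, 10)), "multiple")
  expect_error(write_store(g, p, block_shape = c(10, 10, 10)), "32x32x32")
  expect_equal((prod(default_block_shape("u8")) * kind_bytes("u8")) %% 4096, 0)
  expect_equal((prod(default_block_shape("rgba")) * kind_bytes("rgba")) %% 4096,
               0)
})

test_that("write/open round-trips exactly for every value kind", {
  set.seed(51)
  kinds <- list(u8 = 255, u16 = 65535, u32 = 4294967295, f32 = 1)
  for (kind in names(kinds)) {
    n <- 30^3
    vals <- if (kind == "f32") {
      # snap to representable float32 so the round-trip can be exact
      raw4 <- writeBin(stats::runif(n), raw(), size = 4)
      array(readBin(raw4, "double", n, size = 4), c(30, 30, 30))
    } else {
      array(floor(stats::runif(n) * (kinds[[kind]] + 1)), c(30, 30, 30))
    }
    v <- voxvol_from_array(vals, kind = kind, voxel_size = c(2, 1, 0.5))
    p <- tempfile(fileext = ".blk")
    write_store(v, p)
    lz <- open_store(p)
    back <- store_to_memory(lz)
    expect_identical(back$values, v$values)
    expect_same_domain(back$domain, v$domain)
    expect_equal(back$voxel_size, v$voxel_size)
    unlink(p)
  }
  # rgba
  rgb <- make_rgb_phantom(c(20, 20, 20))
  p <- tempfile(fileext = ".blk")
  write_store(rgb, p)
  expect_identical(store_to_memory(open_store(p))$values, rgb$values)
  unlink(p)
})

test_that("LUT geometry: 100^3 u8 at 32^3 blocks is a 4x4x4 table", {
  g <- make_gradient_volume(c(100, 100, 100), kind = "u8")
  p <- tempfile(fileext = ".blk")
  write_store(g, p)
  lz <- open_store(p)
  expect_equal(lz$lazy$nblocks, c(4L, 4L, 4L))
  expect_equal(length(lz$lazy$lut), 64L)
  expect_true(all(lz$lazy$lut > 0))   # full box: every block present
  unlink(p)
})

test_that("blocks wholly outside the domain are absent and cost no bytes", {
  sph <- make_sphere_phantom(c(100, 100, 100), radius = 40)
  p <- tempfile(fileext = ".blk")
  write_store(sph, p)
  lz <- open_store(p)
  lut <- lz$lazy$lut
  nb <- lz$lazy$nblocks
  # oracle: a block is needed iff some domain voxel falls in it
  dm <- domain_to_mask(sph$domain)
  need <- logical(length(lut))
  idx <- which(dm$mask, arr.ind = TRUE)
  bid <- 1 + (idx[, 1] - 1) %/% 32 +
    nb[1] * ((idx[, 2] - 1) %/% 32 + nb[2] * ((idx[, 3] - 1) %/% 32))
  need[unique(bid)] <- TRUE
  expect_identical(lut > 0, need)
  expect_gt(sum(!need), 0)
  # data region holds exactly the present blocks
  expect_equal(file.size(p) - lz$lazy$data_offset,
               sum(need) * lz$lazy$block_bytes)
  unlink(p)
})

test_that("sparse domains give proportionally small files", {
  # two small blobs in the far corners of a wide box: the file must pay for
  # the blocks the domain intersects, never for the empty bulk between them
  b1 <- random_blob_domain(c(20, 20, 20), n_blobs = 1, seed = 52)
  b2 <- domain_translate(random_blob_domain(c(20, 20, 20), n_blobs = 1,
                                            seed = 53), 140, 140, 140)
  dom <- domain_binary_op(b1, b2, "union")
  dm <- domain_to_mask(dom)
  v <- voxvol_from_array(array(7, dim(dm$mask)), origin = dm$origin,
                         mask = dm$mask, kind = "u8")
  p <- tempfile(fileext = ".blk")
  write_store(v, p)
  lz <- open_store(p)
  present <- sum(lz$lazy$lut > 0)
  expect_lt(present / length(lz$lazy$lut), 0.2)
  expect_equal(file.size(p),
               lz$lazy$data_offset + present * lz$lazy$block_bytes)
  unlink(p)
})

test_that("reading one voxel touches exactly one block", {
  g <- make_gradient_volume(c(100, 100, 100), kind = "u8")
  p <- tempfile(fileext = ".blk")
  write_store(g, p)
  lz <- open_store(p)
  v <- value_at(lz, c(50, 50, 50))
  expect_equal(v$value, value_at(g, c(50, 50, 50))$value)
  expect_equal(store_block_stats(lz)$last, 1L)
  unlink(p)
})

test_that("a z-plane section touches at most the 16 blocks of one slab", {
  g <- make_gradient_volume(c(100, 100, 100), kind = "u16")
  p <- tempfile(fileext = ".blk")
  write_store(g, p, block_shape = c(32, 32, 32))  # 65536 B blocks
  lz <- open_store(p)
  sec <- cut_section(lz, view_spec(dist = 50))
  expect_lte(store_block_stats(lz)$last, 16L)
  expect_equal(length(lz$lazy$lut), 64L)
  unlink(p)
})

test_that("lazy store and in-memory volume answer identically", {
  sph <- make_sphere_phantom(c(60, 60, 60), radius = 25, kind = "u8")
  p <- tempfile(fileext = ".blk")
  write_store(sph, p)
  lz <- open_store(p)
  set.seed(53)
  for (i in 1:5) {
    vw <- resolve_mode(random_view())
    sm <- cut_section(sph, vw)
    sl <- cut_section(lz, vw)
    expect_identical(sl$pixels, sm$pixels)
    expect_identical(sl$inside, sm$inside)
  }
  for (i in 1:50) {
    pt <- sample(-5:65, 3, replace = TRUE)
    expect_identical(value_at(lz, pt), value_at(sph, pt))
  }
  expect_equal(volume_stats(lz), volume_stats(sph))
  unlink(p)
})

test_that("corrupt stores are rejected with a located error", {
  p <- tempfile(fileext = ".blk")
  writeBin(charToRaw("NOTASTORE_______"), p)
  expect_error(open_store(p), "magic at offset 0")
  unlink(p)
})

test_that("streamed TIFF conversion equals the direct store of the volume", {
  sph <- make_sphere_phantom(c(40, 40, 40), radius = 15, kind = "u8")
  td <- tempfile(); dir.create(td)
  write_tiff_stack(sph, td)
  p <- tempfile(fileext = ".blk")
  convert_to_store(td, p, background = 0, threshold = TRUE)
  lz <- open_store(p)
  # thresholding keeps exactly the voxels whose stored grey is nonzero
  dm <- domain_to_mask(sph$domain)
  nonzero <- sum(sph$values[dm$mask != 0] != 0)
  expect_equal(domain_voxel_count(lz$domain), nonzero)
  # values agree wherever both domains contain the voxel
  grid <- which(dm$mask, arr.ind = TRUE)
  keep <- sph$values[grid] != 0
  g <- grid[keep, , drop = FALSE] - 1
  inside <- domain_contains(lz$domain, g[, 1], g[, 2], g[, 3])
  expect_true(all(inside))
  vals <- iip3d:::.values_lookup(lz, g[, 1], g[, 2], g[, 3])
  expect_equal(vals, sph$values[grid][keep])
  unlink(c(p, td), recursive = TRUE)
})

test_that("a 10-plane TIFF stack converts to the expected bounding box", {
  g <- make_gradient_volume(c(64, 64, 10), kind = "u8")
  td <- tempfile(); dir.create(td)
  write_tiff_stack(g, td)
  p <- tempfile(fileext = ".blk")
  convert_to_store(td, p)
  lz <- open_store(p)
  expect_equal(unname(bounding_box(lz)), c(0, 0, 0, 63, 63, 9))
  expect_identical(store_to_memory(lz)$values, g$values)
  unlink(c(p, td), recursive = TRUE)
})
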