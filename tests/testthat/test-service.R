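# one shared server root with a gradient volume and an overlapping compound
local_service <- function(env = parent.frame()) {
  root <- tempfile()
  dir.create(root)
  g <- make_gradient_volume(c(40, 40, 40), kind = "u8")
  write_nifti_volume(g, file.path(root, "grad.nii.gz"))
  comp <- make_compound_phantom(c(40, 40, 40), n_members = 2, overlap = 0.5)
  write_compound_manifest(comp, file.path(root, "comp"))
  withr::defer(unlink(root, recursive = TRUE), envir = env)
  list(root = root, srv = iip3d_server(root = root), grad = g, comp = comp)
}

test_that("request parsing covers commands, case, and failure modes", {
  req <- parse_request("WLZ=/o/a.nii&OBJ=Wlz-grey-value&PAB=190,200,190")
  expect_equal(req$resource, "/o/a.nii")
  expect_equal(req$action, "obj_query")
  expect_equal(req$obj, "Wlz-grey-value")
  expect_equal(req$pab, c(190, 200, 190))

  req <- parse_request("wlz=/x.nii&pit=10&yaw=-20.5&rol=3&dst=7&scl=1.5&fxp=1,2,3&mod=up_is_up&upv=0,0,-1&sel=3,255,0,0&sel=4,128&jtl=1,5&qlt=80")
  expect_equal(req$pitch, 10)
  expect_equal(req$yaw, -20.5)
  expect_equal(req$scale, 1.5)
  expect_equal(req$fixed, c(1, 2, 3))
  expect_equal(req$mode, "up_is_up")
  expect_length(req$sel, 2)
  expect_equal(req$sel[[2]]$a, 128)
  expect_equal(req$action, "tile")
  expect_equal(req$format, "jpeg")
  expect_equal(req$tile, c(1, 5))
  expect_equal(req$quality, 80)

  expect_error(parse_request("OBJ=Wlz-volume"), "missing WLZ")
  expect_error(parse_request("WLZ=/x&FOO=1"), "unknown request command")
  expect_error(parse_request("WLZ=/x&PIT=abc"), "malformed")
  expect_error(parse_request("WLZ=/x&JTL=0,0&CVT=png"), "more than one")
  expect_error(parse_request("WLZ=/x&MOD=sideways"), "unknown viewing mode")
})

test_that("tile grids follow ceiling arithmetic (2 x 3 tiles for 700 x 400)", {
  g <- tile_grid(c(700, 400), c(256, 256))
  expect_equal(g, list(cols = 3, rows = 2, count = 6))
  expect_equal(tile_grid(c(256, 256), c(256, 256))$count, 1)
  g2 <- tile_grid(c(257, 1), c(256, 256))
  expect_equal(c(g2$cols, g2$rows, g2$count), c(2, 1, 2))
})

test_that("tile regions crop edge tiles and reject bad indices", {
  frame <- list(width = 700, height = 400, x_off = 0, y_off = 0)
  r5 <- tile_region(frame, 0, 5, c(256, 256))
  expect_equal(unname(r5[1:4]), c(512, 256, 700 - 512, 400 - 256))
  expect_error(tile_region(frame, 0, 6, c(256, 256)), "out of range")
})

test_that("the worked grey-value query prints the exact reply line", {
  sv <- local_service()
  r <- handle_request(sv$srv, "WLZ=/grad.nii.gz&PAB=3,4,5&OBJ=Wlz-grey-value")
  expect_equal(r$status, 200L)
  v <- (3 + 40 + 500) %% 256
  expect_equal(r$body, sprintf("Wlz-grey-value:%d\n", v))
  # outside the domain the reply is distinct
  r2 <- handle_request(sv$srv, "WLZ=/grad.nii.gz&PAB=100,4,5&OBJ=Wlz-grey-value")
  expect_equal(r2$body, "Wlz-grey-value:outside\n")
})

test_that("object queries answer sizes, boxes, ranges, angles and indices", {
  sv <- local_service()
  q <- function(s) handle_request(sv$srv, s)$body
  expect_equal(q("WLZ=/grad.nii.gz&OBJ=Max-size"), "Max-size:40 40\n")
  expect_equal(q("WLZ=/grad.nii.gz&OBJ=Tile-size"), "Tile-size:256 256\n")
  expect_equal(q("WLZ=/grad.nii.gz&OBJ=Wlz-3d-bounding-box"),
               "Wlz-3d-bounding-box:0 0 0 39 39 39\n")
  expect_equal(q("WLZ=/grad.nii.gz&OBJ=Wlz-distance-range"),
               "Wlz-distance-range:0 39\n")
  expect_equal(q("WLZ=/grad.nii.gz&OBJ=Wlz-volume"),
               sprintf("Wlz-volume:%d\n", 40^3))
  expect_equal(q("WLZ=/grad.nii.gz&OBJ=IIP-server"),
               sprintf("IIP-server:IIP3D/%s\n", packageVersion("iip3d")))
  expect_equal(q("WLZ=/grad.nii.gz&PIT=30&YAW=40&MOD=statue&OBJ=Wlz-sectioning-angles"),
               "Wlz-sectioning-angles:30 40 0\n")
  # up_is_up echoes the resolved roll
  rv <- resolve_mode(view_spec(pitch = 30, yaw = 40, mode = "up_is_up"))
  expect_equal(q("WLZ=/grad.nii.gz&PIT=30&YAW=40&MOD=up_is_up&OBJ=Wlz-sectioning-angles"),
               sprintf("Wlz-sectioning-angles:%.8g %.8g %.8g\n",
                       rv$pitch, rv$yaw, rv$roll))
  # compound foreground indices at a lens point
  c0 <- bounding_box(member(sv$comp, 0))
  c1 <- bounding_box(member(sv$comp, 1))
  lens <- floor((floor((c0[1:3] + c0[4:6]) / 2) +
                   floor((c1[1:3] + c1[4:6]) / 2)) / 2)
  expect_equal(q(sprintf("WLZ=/comp/compound.json&PAB=%d,%d,%d&OBJ=Wlz-foreground-objects",
                         lens[1], lens[2], lens[3])),
               "Wlz-foreground-objects:0 1\n")
  # errors: missing point, unknown query
  expect_equal(handle_request(sv$srv,
    "WLZ=/grad.nii.gz&OBJ=Wlz-grey-value")$status, 400L)
  expect_equal(handle_request(sv$srv,
    "WLZ=/grad.nii.gz&OBJ=Wlz-nonsense")$status, 400L)
})

test_that("2D/3D coordinate queries are mutually consistent", {
  sv <- local_service()
  q <- function(s) handle_request(sv$srv, s)$body
  view <- "PIT=25&YAW=-40&ROL=10&DST=4&FXP=20,20,20"
  # pick a screen point, lift it to 3D, project it back
  co <- q(sprintf("WLZ=/grad.nii.gz&%s&PRT=12,9&OBJ=Wlz-coordinate-3D", view))
  p3 <- as.numeric(strsplit(sub("^[^:]*:", "", co), " ")[[1]])
  tr <- q(sprintf("WLZ=/grad.nii.gz&%s&PAB=%.10g,%.10g,%.10g&OBJ=Wlz-transformed-coordinate-3d",
                  view, p3[1], p3[2], p3[3]))
  xy <- as.numeric(strsplit(sub("^[^:]*:", "", tr), " ")[[1]])
  expect_equal(xy[1:2], c(12, 9), tolerance = 1e-4)
  expect_lt(abs(xy[3]), 1e-4)
})

test_that("tile mosaic equals the CVT full section pixelwise (lossless)", {
  sv <- local_service()
  view <- "PIT=20&YAW=30&DST=2&FXP=20,20,20"
  cvt <- handle_request(sv$srv, sprintf("WLZ=/grad.nii.gz&%s&CVT=png", view))
  full <- decode_raster(cvt$body, "png")
  g <- sv$grad
  frame <- section_frame(bounding_box(g),
                         build_transform(view_spec(fixed = c(20, 20, 20),
                                                   pitch = 20, yaw = 30,
                                                   dist = 2)))
  ts <- c(16L, 16L)
  sv$srv$tile_size <- ts
  grid <- tile_grid(c(frame$width, frame$height), ts)
  mosaic <- array(NA_real_, c(frame$height, frame$width, 4))
  for (idx in seq_len(grid$count) - 1L) {
    resp <- handle_request(sv$srv, sprintf("WLZ=/grad.nii.gz&%s&PTL=0,%d",
                                           view, idx))
    tile <- decode_raster(resp$body, "png")
    x0 <- (idx %% grid$cols) * ts[1]
    y0 <- (idx %/% grid$cols) * ts[2]
    mosaic[y0 + seq_len(dim(tile)[1]), x0 + seq_len(dim(tile)[2]), ] <- tile
  }
  expect_equal(mosaic, full)
})

test_that("CVT at level 1 equals downscaling the level-0 CVT", {
  sv <- local_service()
  view <- "WLZ=/grad.nii.gz&PIT=10&YAW=15&DST=1&FXP=20,20,20"
  l0 <- decode_raster(handle_request(sv$srv, paste0(view, "&CVT=png"))$body,
                      "png")
  l1 <- decode_raster(handle_request(sv$srv, paste0(view, "&CVT=png,1"))$body,
                      "png")
  expect_identical(l1, iip3d:::.downscale_rgba(l0, 1))
})

test_that("empty tiles decode to fully transparent PNGs", {
  sv <- local_service()
  # a distance beyond the volume: nothing inside
  r <- handle_request(sv$srv, "WLZ=/grad.nii.gz&DST=200&PTL=0,0")
  img <- decode_raster(r$body, "png")
  expect_true(all(img[, , 4] == 0))
})

test_that("JPEG tiles differ in bytes but stay close to the lossless image", {
  sv <- local_service()
  view <- "WLZ=/grad.nii.gz&DST=20"
  png_r <- handle_request(sv$srv, paste0(view, "&PTL=0,0"))
  jpg_r <- handle_request(sv$srv, paste0(view, "&JTL=0,0"))
  expect_equal(jpg_r$mime, "image/jpeg")
  expect_false(identical(png_r$body, jpg_r$body))
  a <- decode_raster(png_r$body, "png")[, , 1]
  b <- decode_raster(jpg_r$body, "jpeg")[, , 1]
  mse <- mean((a - b)^2)
  psnr <- 10 * log10(255^2 / max(mse, 1e-12))
  expect_gt(psnr, 30)
  # quality changes the bytes
  jpg_low <- handle_request(sv$srv, paste0(view, "&JTL=0,0&QLT=30"))
  expect_false(identical(jpg_r$body, jpg_low$body))
})

test_that("raw tiles carry the uncompressed display raster", {
  sv <- local_service()
  r <- handle_request(sv$srv, "WLZ=/grad.nii.gz&DST=5&TIL=0,0")
  expect_equal(r$mime, "application/octet-stream")
  img <- decode_raster(r$body, "raw", dims = c(40, 40))
  sec <- cut_section(sv$grad, view_spec(dist = 5))
  expect_equal(img[, , 1], sec$pixels)
  expect_true(all(img[, , 4] == 255))
})

test_that("responses are deterministic and cached byte-identically", {
  sv <- local_service()
  q <- "WLZ=/grad.nii.gz&PIT=33&YAW=-12&DST=7&FXP=20,20,20&PTL=0,0"
  r1 <- handle_request(sv$srv, q)
  r2 <- handle_request(sv$srv, q)
  expect_identical(r1$body, r2$body)
  expect_gt(sv$srv$tiles$hits, 0)
  # bypassing every cache gives the same bytes
  fresh <- iip3d_server(root = sv$root)
  r3 <- handle_request(fresh, q)
  expect_identical(r1$body, r3$body)
})

test_that("a perturbed yaw misses the cache yet stays pixel-correct", {
  sv <- local_service()
  base <- "WLZ=/grad.nii.gz&FXP=20,20,20&DST=3&PIT=10&YAW=%.7g&PTL=0,0"
  r1 <- handle_request(sv$srv, sprintf(base, 25))
  misses_before <- sv$srv$tiles$misses
  set.seed(61)
  eps <- stats::runif(1, 0, 1)
  r2 <- handle_request(sv$srv, sprintf(base, 25 + eps))
  expect_equal(sv$srv$tiles$misses, misses_before + 1L)
  expect_false(identical(r1$body, r2$body))
  # and the perturbed tile is exactly what a direct cut produces
  vw <- view_spec(fixed = c(20, 20, 20), dist = 3, pitch = 10, yaw = 25 + eps)
  t <- build_transform(vw)
  frame <- section_frame(bounding_box(sv$grad), t)
  reg <- tile_region(frame, 0, 0, sv$srv$tile_size)
  sec <- cut_section(sv$grad, vw, region = reg, frame = frame)
  img <- decode_raster(r2$body, "png")
  expect_equal(img[, , 1][sec$inside], sec$pixels[sec$inside])
  expect_equal(img[, , 4], ifelse(sec$inside, 255, 0))
})

test_that("the tile cache evicts least-recently-used entries first", {
  lru <- iip3d:::new_lru(2)
  iip3d:::lru_set(lru, "a", 1)
  iip3d:::lru_set(lru, "b", 2)
  invisible(iip3d:::lru_get(lru, "a"))   # refresh a; b is now LRU
  iip3d:::lru_set(lru, "c", 3)
  expect_equal(lru$evicted, "b")
  expect_null(iip3d:::lru_get(lru, "b"))
  expect_equal(iip3d:::lru_get(lru, "a"), 1)
})

test_that("transform and object caches are keyed by view and resource", {
  sv <- local_service()
  q1 <- "WLZ=/grad.nii.gz&PIT=10&YAW=20&OBJ=Max-size"
  invisible(handle_request(sv$srv, q1))
  invisible(handle_request(sv$srv, q1))
  expect_gt(sv$srv$objects$hits, 0)
  expect_gt(sv$srv$transforms$hits, 0)
  tm <- sv$srv$transforms$misses
  invisible(handle_request(sv$srv, "WLZ=/grad.nii.gz&PIT=10&YAW=20.001&OBJ=Max-size"))
  expect_equal(sv$srv$transforms$misses, tm + 1L)
})

test_that("parallel clients receive byte-identical responses to a serial run", {
  sv <- local_service()
  queries <- c("WLZ=/grad.nii.gz&DST=5&PTL=0,0",
               "WLZ=/grad.nii.gz&DST=5&OBJ=Max-size",
               "WLZ=/grad.nii.gz&PIT=30&DST=2&FXP=20,20,20&PTL=0,0",
               "WLZ=/grad.nii.gz&DST=5&CVT=png")
  serial <- lapply(queries, function(q) handle_request(sv$srv, q)$body)
  par <- parallel::mclapply(rep(queries, 3), function(q) {
    handle_request(iip3d_server(root = sv$root), q)$body
  }, mc.cores = 2)
  expect_identical(par, rep(serial, 3))
})

test_that("resource resolution confines paths to the object root", {
  sv <- local_service()
  expect_equal(handle_request(sv$srv, "WLZ=/../../etc/passwd&OBJ=Max-size")$status,
               404L)
  expect_equal(handle_request(sv$srv, "WLZ=/missing.nii.gz&OBJ=Max-size")$status,
               404L)
  r <- handle_request(sv$srv, "WLZ=grad.nii.gz&OBJ=Max-size")
  expect_equal(r$status, 200L)
})

test_that("substring routing picks the first match, else the default", {
  tab <- routing_table(rules = list(list(match = "/emb/", backend = "B1"),
                                    list(match = "emb", backend = "B2")),
                       default = "B0")
  expect_equal(route_request("WLZ=/emb/a.nii&OBJ=Max-size", tab), "B1")
  expect_equal(route_request("WLZ=/embryo.nii", tab), "B2")
  expect_equal(route_request("WLZ=/other.nii", tab), "B0")
  # order sensitivity: both rules match this one, the earlier wins
  expect_equal(route_request("xx/emb/yy", tab), "B1")
})

test_that("server config files round-trip through JSON", {
  root <- tempfile(); dir.create(root)
  cfgp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(root = root, tile_size = c(64, 64),
                            jpeg_quality = 80, tile_cache = 5, port = 9123,
                            routing = list(rules = data.frame(
                              match = "/a/", backend = "B1"),
                              default_backend = "B0")),
                       cfgp, auto_unbox = TRUE)
  cfg <- iip3d_server_from_config(cfgp)
  expect_equal(cfg$port, 9123)
  expect_equal(cfg$server$tile_size, c(64L, 64L))
  expect_equal(route_request("WLZ=/a/x", cfg$server$routing), "B1")
  expect_equal(route_request("WLZ=/b/x", cfg$server$routing), "B0")
  unlink(c(root, cfgp), recursive = TRUE)
})
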