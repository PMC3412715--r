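#' Tile service: protocol, caching, routing
#'
#' The service answers HTTP-style query strings of `&`-separated `CMD=value`
#' pairs (command tokens case-insensitive). A request names a resource
#' (`WLZ=path`, resolved under the server's object root), sets view parameters
#' (`FXP`, `PIT`, `YAW`, `ROL`, `DST`, `SCL`, `MOD`, `UPV`, `FX2`, `LNA`) and
#' any number of `SEL` overlay selections, then asks for exactly one thing:
#' a compressed or raw tile (`JTL=level,index`, `PTL=level,index`,
#' `TIL=level,index`), a full section (`CVT=png|jpeg[,level]`) or an object
#' query (`OBJ=name`, optionally with a probe point `PRT=x,y` in section-frame
#' pixels or `PAB=k,l,p` in 3D).
#'
#' Responses are deterministic functions of (resource bytes, query string,
#' configuration): PNG tiles carry an alpha channel that is 0 wherever the
#' section leaves the object's domain, JPEG tiles show background there, raw
#' tiles are the uncompressed display raster, and query replies are
#' `Name:value` text lines with space-separated values.
#'
#' Three caches accelerate repeated access: encoded tiles by tile key, opened
#' objects by resource path, and resolved viewing transforms by view digest.
#' All three are LRU with configurable capacities; any view parameter change
#' changes the digest and is a miss.
#'
#' @name tile-service
NULL

.PROTOCOL_ID <- "IIP3D"

# ---- LRU cache ----------------------------------------------------------

new_lru <- function(capacity) {
  e <- new.env(parent = emptyenv())
  e$capacity <- as.integer(capacity)
  e$store <- new.env(parent = emptyenv())
  e$order <- character(0)   # least recent first
  e$hits <- 0L
  e$misses <- 0L
  e$evicted <- character(0)
  class(e) <- "lru_cache"
  e
}

lru_get <- function(cache, key) {
  if (!exists(key, envir = cache$store, inherits = FALSE)) {
    cache$misses <- cache$misses + 1L
    return(NULL)
  }
  cache$hits <- cache$hits + 1L
  cache$order <- c(setdiff(cache$order, key), key)
  get(key, envir = cache$store, inherits = FALSE)
}

lru_set <- function(cache, key, value) {
  if (!exists(key, envir = cache$store, inherits = FALSE) &&
      length(cache$order) >= cache$capacity) {
    victim <- cache$order[1L]
    rm(list = victim, envir = cache$store)
    cache$order <- cache$order[-1L]
    cache$evicted <- c(cache$evicted, victim)
  }
  assign(key, value, envir = cache$store)
  cache$order <- c(setdiff(cache$order, key), key)
  invisible(value)
}

#' Fetch from a cache or compute and remember
#'
#' On a miss `compute()` is evaluated and its value stored; cached values are
#' byte-identical to recomputation because every computation in the service is
#' a pure function of its key.
#'
#' @param cache An LRU cache from the server.
#' @param key Character key.
#' @param compute Zero-argument function.
#' @export
cache_get_or_compute <- function(cache, key, compute) {
  v <- lru_get(cache, key)
  if (is.null(v)) {
    v <- compute()
    lru_set(cache, key, v)
  }
  v
}

# ---- server state -------------------------------------------------------

#' Create a tile server
#'
#' @param root Directory under which `WLZ` resource paths are resolved; paths
#'   escaping the root are rejected.
#' @param tile_size Tile extents `(tw, th)` in pixels, default 256 x 256.
#' @param jpeg_quality JPEG encoder quality 1..100, pinned so encoded bytes
#'   are deterministic per installation.
#' @param tile_cache,object_cache,transform_cache LRU capacities of the three
#'   caching levels (encoded tiles, opened objects, resolved transforms).
#' @param routing Optional routing table from [routing_table()] (proxy mode).
#' @return An `iip3d_server` environment.
#' @export
iip3d_server <- function(root = ".", tile_size = c(256L, 256L),
                         jpeg_quality = 75L, tile_cache = 128L,
                         object_cache = 8L, transform_cache = 64L,
                         routing = NULL) {
  srv <- new.env(parent = emptyenv())
  srv$root <- normalizePath(root, mustWork = TRUE)
  srv$tile_size <- as.integer(tile_size)
  srv$jpeg_quality <- as.integer(jpeg_quality)
  srv$tiles <- new_lru(tile_cache)
  srv$objects <- new_lru(object_cache)
  srv$transforms <- new_lru(transform_cache)
  srv$routing <- routing
  class(srv) <- "iip3d_server"
  srv
}

#' Create a server from a JSON configuration file
#'
#' Recognised fields: `root`, `tile_size`, `jpeg_quality`, `tile_cache`,
#' `object_cache`, `transform_cache`, `port`, and `routing` (list of
#' `{"match": substring, "backend": id}` rules plus `"default_backend"`).
#'
#' @param path JSON file.
#' @return List with `server` (an `iip3d_server`) and `port`.
#' @export
iip3d_server_from_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  routing <- NULL
  if (!is.null(cfg$routing)) {
    routing <- routing_table(rules = Map(list,
                                         match = cfg$routing$rules$match,
                                         backend = cfg$routing$rules$backend),
                             default = cfg$routing$default_backend)
  }
  srv <- iip3d_server(
    root = cfg$root %||% ".",
    tile_size = cfg$tile_size %||% c(256L, 256L),
    jpeg_quality = cfg$jpeg_quality %||% 75L,
    tile_cache = cfg$tile_cache %||% 128L,
    object_cache = cfg$object_cache %||% 8L,
    transform_cache = cfg$transform_cache %||% 64L,
    routing = routing)
  list(server = srv, port = cfg$port %||% 9000L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- request parsing ----------------------------------------------------

.num_or_fail <- function(s, cmd, n = 1) {
  v <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
  if (length(v) != n || anyNA(v)) {
    stop(sprintf("malformed %s value: '%s'", cmd, s), call. = FALSE)
  }
  v
}

#' Parse an IIP3D query string
#'
#' @param query Query string of `&`-separated `CMD=value` pairs; command
#'   tokens are case-insensitive.
#' @return An `iip3d_request`: resource path, view fields, SEL stack, action
#'   (`tile`, `full_section`, `obj_query` or `none`) with its parameters, and
#'   optional probe points `prt` / `pab`.
#' @export
parse_request <- function(query) {
  query <- sub("^[^?]*\\?", "", query)
  parts <- strsplit(query, "&", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  req <- list(resource = NULL,
              fixed = c(0, 0, 0), pitch = 0, yaw = 0, roll = 0, dist = 0,
              scale = 1, mode = "absolute", up = c(0, 0, -1), fixed2 = NULL,
              line_angle = 0, sel = list(), quality = NULL,
              action = "none", tile = NULL, format = NULL, cvt_level = 0L,
              prt = NULL, pab = NULL, obj = NULL)
  set_action <- function(a) {
    if (req$action != "none") {
      stop("request contains more than one information request", call. = FALSE)
    }
    a
  }
  for (part in parts) {
    eq <- regexpr("=", part, fixed = TRUE)
    if (eq < 0) stop("malformed request component: '", part, "'", call. = FALSE)
    cmd <- toupper(substr(part, 1, eq - 1))
    val <- substr(part, eq + 1, nchar(part))
    switch(cmd,
      WLZ = req$resource <- val,
      DST = req$dist <- .num_or_fail(val, cmd),
      PIT = req$pitch <- .num_or_fail(val, cmd),
      YAW = req$yaw <- .num_or_fail(val, cmd),
      ROL = req$roll <- .num_or_fail(val, cmd),
      SCL = {
        req$scale <- .num_or_fail(val, cmd)
        if (req$scale <= 0) stop("SCL must be positive", call. = FALSE)
      },
      FXP = req$fixed <- .num_or_fail(val, cmd, 3),
      FX2 = req$fixed2 <- .num_or_fail(val, cmd, 3),
      UPV = req$up <- .num_or_fail(val, cmd, 3),
      LNA = req$line_angle <- .num_or_fail(val, cmd),
      QLT = req$quality <- .num_or_fail(val, cmd),
      MOD = {
        mode <- tolower(val)
        mode <- c(absolute = "absolute", statue = "statue",
                  up_is_up = "up_is_up", upisup = "up_is_up",
                  fixed_line = "fixed_line", fixedline = "fixed_line")[mode]
        if (is.na(mode)) stop("unknown viewing mode: ", val, call. = FALSE)
        req$mode <- unname(mode)
      },
      SEL = req$sel <- c(req$sel, list(parse_sel(val))),
      JTL = {
        req$action <- set_action("tile"); req$format <- "jpeg"
        req$tile <- .num_or_fail(val, cmd, 2)
      },
      PTL = {
        req$action <- set_action("tile"); req$format <- "png"
        req$tile <- .num_or_fail(val, cmd, 2)
      },
      TIL = {
        req$action <- set_action("tile"); req$format <- "raw"
        req$tile <- .num_or_fail(val, cmd, 2)
      },
      CVT = {
        req$action <- set_action("full_section")
        cv <- strsplit(val, ",", fixed = TRUE)[[1]]
        fmt <- tolower(cv[1])
        if (!fmt %in% c("png", "jpeg")) {
          stop("CVT format must be png or jpeg, got '", cv[1], "'", call. = FALSE)
        }
        req$format <- fmt
        if (length(cv) > 1L) req$cvt_level <- .num_or_fail(cv[2], cmd)
      },
      OBJ = {
        req$action <- set_action("obj_query")
        req$obj <- val
      },
      PRT = req$prt <- .num_or_fail(val, cmd, 2),
      PAB = req$pab <- .num_or_fail(val, cmd, 3),
      stop("unknown request command: ", cmd, call. = FALSE))
  }
  if (req$action != "none" && is.null(req$resource)) {
    stop("missing WLZ resource specifier before the information request",
         call. = FALSE)
  }
  structure(req, class = "iip3d_request")
}

#' View specification carried by a request
#' @param req An `iip3d_request`.
#' @return A `view_spec`.
#' @export
request_view <- function(req) {
  view_spec(fixed = req$fixed, pitch = req$pitch, yaw = req$yaw,
            roll = req$roll, dist = req$dist, scale = req$scale,
            mode = req$mode, up = req$up, fixed2 = req$fixed2,
            line_angle = req$line_angle)
}

# ---- resources ----------------------------------------------------------

resolve_resource_path <- function(srv, path) {
  rel <- sub("^/+", "", path)
  full <- file.path(srv$root, rel)
  if (!file.exists(full)) stop("unknown resource: ", path, call. = FALSE)
  norm <- normalizePath(full, mustWork = TRUE)
  root <- paste0(srv$root, .Platform$file.sep)
  if (!startsWith(paste0(norm, .Platform$file.sep), root)) {
    stop("resource path escapes the object root: ", path, call. = FALSE)
  }
  norm
}

#' Load (and cache) a resource by its protocol path
#'
#' Resolves the path under the server root (rejecting traversal outside it),
#' dispatches on format — block store (`.blk`), NIfTI (`.nii`/`.nii.gz`,
#' `.labels.nii*` for label images), TIFF stack directory, compound manifest
#' (`.json`) — and keeps the opened object in the server's object cache.
#'
#' @param srv An `iip3d_server`.
#' @param path Resource path as given in a `WLZ` command.
#' @return A `voxvol` or `compound3d`.
#' @export
load_resource <- function(srv, path) {
  norm <- resolve_resource_path(srv, path)
  cache_get_or_compute(srv$objects, norm, function() .open_resource(norm))
}

.open_resource <- function(path) {
  if (dir.exists(path)) return(read_tiff_stack(path))
  lower <- tolower(path)
  if (endsWith(lower, ".blk")) return(open_store(path))
  if (endsWith(lower, ".json")) return(read_compound_manifest(path))
  if (grepl("\\.labels\\.nii(\\.gz)?$", lower)) {
    return(read_labelled_volume(path))
  }
  if (grepl("\\.nii(\\.gz)?$", lower)) return(read_nifti_volume(path))
  if (grepl("\\.tiff?$", lower)) return(read_tiff_stack(path))
  stop("unsupported resource format: ", path, call. = FALSE)
}

.resource_transform <- function(srv, req) {
  view <- request_view(req)
  key <- digest::digest(view[c("fixed", "pitch", "yaw", "roll", "dist",
                               "scale", "mode", "up", "fixed2", "line_angle")])
  cache_get_or_compute(srv$transforms, key, function() build_transform(view))
}

# ---- tiles --------------------------------------------------------------

#' Tile grid covering a section
#'
#' Tiles are numbered row-major from 0; edge tiles are cropped to the section.
#'
#' @param section_size Section raster extents `(w, h)` in pixels.
#' @param tile_size Tile extents `(tw, th)`.
#' @return List with `cols`, `rows`, `count`.
#' @export
tile_grid <- function(section_size, tile_size = c(256L, 256L)) {
  stopifnot(all(section_size >= 1), all(tile_size >= 1))
  cols <- ceiling(section_size[1] / tile_size[1])
  rows <- ceiling(section_size[2] / tile_size[2])
  list(cols = cols, rows = rows, count = cols * rows)
}

#' Pixel region of one tile at a resolution level
#'
#' @param frame A [section_frame()].
#' @param level Resolution level.
#' @param index Row-major tile index from 0.
#' @param tile_size Tile extents `(tw, th)`.
#' @return Region `c(x, y, w, h)` in level-0 section-frame pixels, plus the
#'   grid as attribute `grid`.
#' @export
tile_region <- function(frame, level, index, tile_size = c(256L, 256L)) {
  step <- 2^level
  lw <- ceiling(frame$width / step)
  lh <- ceiling(frame$height / step)
  g <- tile_grid(c(lw, lh), tile_size)
  if (index < 0 || index >= g$count) {
    stop(sprintf("tile index %d out of range (grid %dx%d = %d tiles)",
                 index, g$cols, g$rows, g$count), call. = FALSE)
  }
  col <- index %% g$cols
  row <- index %/% g$cols
  x <- col * tile_size[1]
  y <- row * tile_size[2]
  w <- min(tile_size[1], lw - x)
  h <- min(tile_size[2], lh - y)
  structure(c(x * step, y * step, w * step, h * step), grid = g)
}

# RGBA display raster (h x w x 4, 0..255) for a request: either a SEL overlay
# stack or the resource's own section
.render_raster <- function(resource, req, t, frame, region, level) {
  rv <- t$view
  if (length(req$sel) > 0L) {
    render_sel_stack(resource, req$sel, rv, region = region, level = level,
                     frame = frame)
  } else if (inherits(resource, "compound3d")) {
    # un-selected compound: all members opaque white, painted in index order
    sels <- lapply(seq_len(n_members(resource)) - 1L,
                   function(i) parse_sel(as.character(i)))
    render_sel_stack(resource, sels, rv, region = region, level = level,
                     frame = frame)
  } else {
    sec <- cut_section(resource, rv, region = region, level = level,
                       frame = frame)
    g <- section_display(sec)
    if (length(dim(g)) == 3L) {
      a <- g[, , 4]
      a[!sec$inside] <- 0
      g[, , 4] <- a
      g
    } else {
      out <- array(0, c(dim(g), 4))
      for (ch in 1:3) out[, , ch] <- g
      out[, , 4] <- ifelse(sec$inside, 255, 0)
      out
    }
  }
}

#' Encode an RGBA display raster
#'
#' @param raster `h x w x 4` array, channels 0..255.
#' @param format `"png"` (lossless, keeps alpha), `"jpeg"` (alpha composited
#'   over black background) or `"raw"` (interleaved RGBA bytes, row-major).
#' @param quality JPEG quality 1..100.
#' @return List with `bytes` (raw vector) and `mime`.
#' @export
encode_raster <- function(raster, format = c("png", "jpeg", "raw"),
                          quality = 75L) {
  format <- match.arg(format)
  stopifnot(length(dim(raster)) == 3L, dim(raster)[3] == 4L)
  switch(format,
    png = list(bytes = png::writePNG(raster / 255), mime = "image/png"),
    jpeg = {
      rgb <- raster[, , 1:3, drop = FALSE] / 255 * rep(raster[, , 4] / 255, 3)
      list(bytes = jpeg::writeJPEG(rgb, quality = quality / 100),
           mime = "image/jpeg")
    },
    raw = {
      v <- as.integer(aperm(raster, c(3, 2, 1)))  # channel, then x, then y
      list(bytes = as.raw(v), mime = "application/octet-stream")
    })
}

#' Decode an encoded tile back to an RGBA raster (0..255)
#'
#' Test/measurement helper, the inverse of [encode_raster()] for png and raw.
#'
#' @param bytes Raw vector.
#' @param format `"png"`, `"jpeg"` or `"raw"`.
#' @param dims For `"raw"`, the `c(h, w)` of the raster.
#' @return `h x w x 4` array (jpeg: alpha 255).
#' @export
decode_raster <- function(bytes, format, dims = NULL) {
  switch(format,
    png = {
      img <- png::readPNG(bytes)
      if (length(dim(img)) == 2L) {
        out <- array(255, c(dim(img), 4))
        for (ch in 1:3) out[, , ch] <- img * 255
        out
      } else if (dim(img)[3] == 4L) {
        img * 255
      } else {
        out <- array(255, c(dim(img)[1:2], 4))
        out[, , 1:dim(img)[3]] <- img[, , ] * 255
        out
      }
    },
    jpeg = {
      img <- jpeg::readJPEG(bytes)
      out <- array(255, c(dim(img)[1:2], 4))
      if (length(dim(img)) == 2L) {
        for (ch in 1:3) out[, , ch] <- img * 255
      } else out[, , 1:3] <- img * 255
      out
    },
    raw = {
      v <- as.integer(bytes)
      aperm(array(v, c(4, dims[2], dims[1])), c(3, 2, 1))
    })
}

#' Fetch one encoded tile
#'
#' Cuts (and, with a SEL stack, composites) the tile's region at the given
#' level and encodes it. Responses for equal tile keys are byte-identical;
#' the server front end caches them by key.
#'
#' @param resource A `voxvol` or `compound3d`.
#' @param view A `view_spec`.
#' @param sel List of `sel_entry` (possibly empty).
#' @param level Resolution level.
#' @param index Row-major tile index from 0.
#' @param format `"png"`, `"jpeg"` or `"raw"`.
#' @param quality JPEG quality.
#' @param tile_size Tile extents.
#' @return List with `bytes`, `mime` and the tile `region`.
#' @export
get_tile <- function(resource, view, sel = list(), level = 0, index = 0,
                     format = "png", quality = 75L,
                     tile_size = c(256L, 256L)) {
  t <- build_transform(view)
  frame <- section_frame(bounding_box(resource), t)
  region <- tile_region(frame, level, index, tile_size)
  req <- list(sel = sel)
  raster <- .render_raster(resource, req, t, frame, region, level)
  out <- encode_raster(raster, format, quality)
  out$region <- region
  out
}

#' Fetch the full section image
#'
#' The full-section request delivers the whole frame at a pyramid level; the
#' level-`L` raster is the box-filtered reduction of the level-0 cut, so it
#' matches [downscale()] of the full-resolution section exactly.
#'
#' @inheritParams get_tile
#' @return List with `bytes`, `mime`.
#' @export
get_full_section <- function(resource, view, sel = list(), level = 0,
                             format = "png", quality = 75L) {
  t <- build_transform(view)
  frame <- section_frame(bounding_box(resource), t)
  raster <- .render_raster(resource, list(sel = sel), t, frame, NULL, 0)
  if (level > 0) {
    raster <- .downscale_rgba(raster, level)
  }
  encode_raster(raster, format, quality)
}

.downscale_rgba <- function(raster, levels) {
  f <- 2^levels
  shrink <- function(m) {
    gr <- floor((seq_len(nrow(m)) - 1) / f)
    gc <- floor((seq_len(ncol(m)) - 1) / f)
    s <- t(rowsum(t(rowsum(m, gr)), gc))
    cnt <- outer(as.numeric(table(gr)), as.numeric(table(gc)))
    floor(s / cnt + 0.5)
  }
  ch <- lapply(1:4, function(i) shrink(raster[, , i]))
  array(unlist(ch), c(dim(ch[[1]]), 4))
}

# ---- object queries -----------------------------------------------------

.fmt_vals <- function(...) paste(vapply(c(...), function(v) {
  if (is.numeric(v)) sprintf("%.8g", v) else as.character(v)
}, character(1)), collapse = " ")

.query_point3 <- function(req, t, frame) {
  if (!is.null(req$pab)) return(req$pab)
  if (!is.null(req$prt)) return(unproject_point(t, req$prt, frame))
  stop("query needs a point: supply PRT=x,y or PAB=k,l,p", call. = FALSE)
}

#' Answer an object query
#'
#' Implements the protocol's information requests: server identification,
#' section and tile sizes, bounding box (plane, line, column firsts then
#' lasts), 2D-to-3D and 3D-to-2D coordinate transforms, sectioning distance
#' range, resolved sectioning angles, foreground member indices, grey/RGB
#' value, true voxel size and object volume (voxel count). Reply format is
#' `Name:value` with space-separated values, newline-terminated.
#'
#' @param resource A `voxvol` or `compound3d`.
#' @param view A `view_spec`.
#' @param req An `iip3d_request` with `obj` set (and `prt` / `pab` for point
#'   queries).
#' @param tile_size Tile extents reported by `Tile-size`.
#' @return Single reply string, newline-terminated.
#' @export
answer_obj_query <- function(resource, view, req, tile_size = c(256L, 256L)) {
  t <- build_transform(view)
  frame <- section_frame(bounding_box(resource), t)
  name <- req$obj
  bb <- bounding_box(resource)
  value <- switch(name,
    "IIP-server" = sprintf("%s/%s", .PROTOCOL_ID,
                           as.character(utils::packageVersion("iip3d"))),
    "Max-size" = .fmt_vals(frame$width, frame$height),
    "Tile-size" = .fmt_vals(tile_size[1], tile_size[2]),
    "Wlz-3d-bounding-box" = .fmt_vals(bb[["p1"]], bb[["l1"]], bb[["k1"]],
                                      bb[["p2"]], bb[["l2"]], bb[["k2"]]),
    "Wlz-coordinate-3D" = {
      if (is.null(req$prt)) stop("Wlz-coordinate-3D needs PRT=x,y", call. = FALSE)
      .fmt_vals(unproject_point(t, req$prt, frame))
    },
    "Wlz-distance-range" = .fmt_vals(frame$dist_min, frame$dist_max),
    "Wlz-foreground-objects" = {
      p3 <- floor(.query_point3(req, t, frame) + 0.5)
      idx <- if (inherits(resource, "compound3d")) {
        members_at(resource, p3)
      } else {
        if (domain_contains(resource$domain, p3[1], p3[2], p3[3])) 0L
        else integer(0)
      }
      if (length(idx)) .fmt_vals(as.list(idx)) else ""
    },
    "Wlz-grey-value" = {
      if (inherits(resource, "compound3d")) {
        stop("Wlz-grey-value: compound object members carry no values",
             call. = FALSE)
      }
      if (!has_values(resource)) {
        stop("Wlz-grey-value: object has no values", call. = FALSE)
      }
      p3 <- floor(.query_point3(req, t, frame) + 0.5)
      v <- value_at(resource, p3)
      if (!v$inside) "outside" else .fmt_vals(as.list(v$value))
    },
    "Wlz-sectioning-angles" = {
      rv <- resolve_mode(view)
      .fmt_vals(rv$pitch, rv$yaw, rv$roll)
    },
    "Wlz-transformed-coordinate-3d" = {
      if (is.null(req$pab)) {
        stop("Wlz-transformed-coordinate-3d needs PAB=k,l,p", call. = FALSE)
      }
      .fmt_vals(project_point(t, req$pab, frame))
    },
    "Wlz-true-voxel-size" = {
      vs <- if (inherits(resource, "compound3d")) {
        resource$members[[1]]$voxel_size
      } else resource$voxel_size
      .fmt_vals(as.list(vs))
    },
    "Wlz-volume" = {
      n <- if (inherits(resource, "compound3d")) {
        sum(vapply(resource$members,
                   function(m) domain_voxel_count(m$domain), numeric(1)))
      } else volume_stats(resource)$voxel_count
      .fmt_vals(n)
    },
    stop("unknown object query: ", name, call. = FALSE))
  paste0(name, ":", value, "\n")
}

# ---- front door ---------------------------------------------------------

#' Handle one protocol request
#'
#' Parses the query, loads the resource (object cache), resolves the view
#' (transform cache) and dispatches the action; tile responses additionally
#' go through the tile cache keyed by resource, resolved view, SEL stack,
#' level, index, format and quality.
#'
#' @param srv An `iip3d_server`.
#' @param query Query string (anything before `?` is ignored).
#' @return List with `status`, `mime` and `body` (raw vector or character).
#' @export
handle_request <- function(srv, query) {
  req <- tryCatch(parse_request(query), error = function(e) e)
  if (inherits(req, "error")) {
    return(list(status = 400L, mime = "text/plain",
                body = paste0("error:", conditionMessage(req), "\n")))
  }
  if (req$action == "none") {
    return(list(status = 400L, mime = "text/plain",
                body = "error:no information request\n"))
  }
  out <- tryCatch({
    resource <- load_resource(srv, req$resource)
    view <- request_view(req)
    t <- .resource_transform(srv, req)
    switch(req$action,
      obj_query = list(status = 200L, mime = "text/plain",
                       body = answer_obj_query(resource, view, req,
                                               srv$tile_size)),
      tile = {
        quality <- as.integer(req$quality %||% srv$jpeg_quality)
        rv <- resolve_mode(view)
        key <- digest::digest(list(req$resource,
                                   rv[c("fixed", "pitch", "yaw", "roll",
                                        "dist", "scale")],
                                   req$sel, req$tile, req$format, quality,
                                   srv$tile_size))
        enc <- cache_get_or_compute(srv$tiles, key, function() {
          frame <- section_frame(bounding_box(resource), t)
          region <- tile_region(frame, req$tile[1], req$tile[2], srv$tile_size)
          raster <- .render_raster(resource, req, t, frame, region,
                                   req$tile[1])
          encode_raster(raster, req$format, quality)
        })
        list(status = 200L, mime = enc$mime, body = enc$bytes)
      },
      full_section = {
        quality <- as.integer(req$quality %||% srv$jpeg_quality)
        enc <- get_full_section(resource, view, req$sel, req$cvt_level,
                                req$format, quality)
        list(status = 200L, mime = enc$mime, body = enc$bytes)
      })
  }, error = function(e) {
    status <- if (grepl("unknown resource", conditionMessage(e))) 404L else 400L
    list(status = status, mime = "text/plain",
         body = paste0("error:", conditionMessage(e), "\n"))
  })
  out
}

# ---- proxy routing ------------------------------------------------------

#' Build a proxy routing table
#'
#' @param rules Ordered list of `list(match = substring, backend = id)`.
#' @param default Backend id used when no rule matches.
#' @return A `routing_table`.
#' @export
routing_table <- function(rules = list(), default) {
  stopifnot(!missing(default))
  structure(list(rules = rules, default = default), class = "routing_table")
}

#' Route a request to a backend
#'
#' Purely string-level: the first rule whose match string is a substring of
#' the query wins; otherwise the default backend. Any request can be routed —
#' nothing is parsed.
#'
#' @param query Query string.
#' @param table A [routing_table()].
#' @return Backend id.
#' @export
route_request <- function(query, table) {
  stopifnot(inherits(table, "routing_table"))
  for (rule in table$rules) {
    if (grepl(rule$match, query, fixed = TRUE)) return(rule$backend)
  }
  table$default
}

# ---- plain HTTP transport ----------------------------------------------

#' Serve the protocol over HTTP
#'
#' A minimal blocking HTTP/1.1 loop over a listening socket: each `GET`
#' request's query string goes through [handle_request()] (or, in proxy mode
#' with a routing table, is answered with the backend id). Intended for
#' single-user/atlas-development use; run several instances behind a proxy
#' for more.
#'
#' @param srv An `iip3d_server`.
#' @param port TCP port.
#' @param max_requests Stop after this many requests (default unlimited);
#'   mainly for tests.
#' @export
serve_iip3d <- function(srv, port = 9000L, max_requests = Inf) {
  n <- 0
  while (n < max_requests) {
    con <- suppressWarnings(socketConnection(host = "127.0.0.1", port = port,
                                             server = TRUE, blocking = TRUE,
                                             open = "r+b", timeout = 30))
    ok <- tryCatch({
      line <- readLines(con, 1)
      m <- regmatches(line, regexec("^GET\\s+(\\S+)", line))[[1]]
      if (length(m) == 2L) {
        resp <- handle_request(srv, m[2])
        body <- if (is.character(resp$body)) charToRaw(resp$body) else resp$body
        hdr <- sprintf(paste0("HTTP/1.1 %d %s\r\nContent-Type: %s\r\n",
                              "Content-Length: %d\r\nConnection: close\r\n\r\n"),
                       resp$status, if (resp$status == 200L) "OK" else "Error",
                       resp$mime, length(body))
        writeBin(c(charToRaw(hdr), body), con)
      }
      TRUE
    }, error = function(e) TRUE)
    close(con)
    n <- n + 1
  }
  invisible(n)
}
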