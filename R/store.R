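#' Chunked block store for larger-than-memory volumes
#'
#' Grey (or rgba) values are kept on disk in fixed-size cuboidal blocks
#' addressed through a lookup table, while the interval-coded domain is always
#' loaded in full. Sectioning an opened store therefore touches only the
#' blocks the section plane intersects; blocks wholly outside the domain are
#' never written and occupy zero data bytes. Block byte sizes must be integer
#' multiples of the filesystem block size (default 4096) so block reads align
#' with device I/O.
#'
#' File layout (all little-endian):
#' \preformatted{
#'   bytes 0..7    magic "IVBLK3D\0"
#'   int32         format version (1)
#'   int32         value kind (1 u8, 2 u16, 3 u32, 4 f32, 5 rgba)
#'   4 x float64   background (channels beyond the first 0 for grey kinds)
#'   3 x float64   voxel size (sx, sy, sz)
#'   6 x int32     bounding box (k1, l1, p1, k2, l2, p2)
#'   3 x int32     block shape (bk, bl, bp)
#'   int32         filesystem block size the blocks are aligned to
#'   int32         number of domain interval runs
#'   int32         number of present blocks
#'   runs          n x (p, l, k1, k2) int32 — the interval domain
#'   LUT           prod(ceil(extent/block)) int32, plane-major like the data;
#'                 0 = absent block, otherwise 1-based slot in the data region
#'   data          present blocks back to back, each prod(block)*bytes/voxel,
#'                 values column-fastest within the block, partial edge blocks
#'                 padded with background
#' }
#'
#' @name block-store
NULL

.STORE_MAGIC <- charToRaw("IVBLK3D\x01")
.KIND_CODES <- c(u8 = 1L, u16 = 2L, u32 = 3L, f32 = 4L, rgba = 5L)

#' Default block shape for a value kind
#'
#' Chosen so a block is a whole number of 4096-byte filesystem blocks:
#' 32x32x32 for 1-byte voxels, 32x32x16 for 2-byte, 32x32x8 for 4-byte
#' (including rgba).
#'
#' @param kind Value kind.
#' @export
default_block_shape <- function(kind) {
  switch(as.character(kind_info(kind)$bytes * 1),
         "1" = c(32L, 32L, 32L), "2" = c(32L, 32L, 16L), c(32L, 32L, 8L))
}

#' Bytes per voxel of a kind (all channels)
#' @param kind Value kind.
#' @export
kind_bytes <- function(kind) kind_info(kind)$bytes

.check_block_shape <- function(block_shape, kind, fs_block = 4096L) {
  bytes <- prod(block_shape) * kind_bytes(kind)
  if (bytes %% fs_block != 0) {
    stop(sprintf(paste0("block shape %s gives %d bytes per block, not a ",
                        "multiple of the %d-byte filesystem block; try e.g. %s"),
                 paste(block_shape, collapse = "x"), bytes, fs_block,
                 paste(default_block_shape(kind), collapse = "x")),
         call. = FALSE)
  }
  invisible(bytes)
}

.store_geometry <- function(bbox, block_shape) {
  ext <- c(bbox[4] - bbox[1] + 1, bbox[5] - bbox[2] + 1, bbox[6] - bbox[3] + 1)
  nb <- as.integer(ceiling(ext / block_shape))
  list(ext = ext, nblocks = nb, total = prod(nb))
}

#' Write a volume to a block store file
#'
#' @param vol An in-memory `voxvol` with values.
#' @param path Output file path.
#' @param block_shape Block extents `(bk, bl, bp)`; default
#'   [default_block_shape()] for the volume's kind.
#' @param fs_block Filesystem block size the block byte size must divide into.
#' @return `path`, invisibly.
#' @export
write_store <- function(vol, path, block_shape = NULL, fs_block = 4096L) {
  stopifnot(inherits(vol, "voxvol"), !is.null(vol$values))
  if (is.null(block_shape)) block_shape <- default_block_shape(vol$kind)
  block_shape <- as.integer(block_shape)
  .check_block_shape(block_shape, vol$kind, fs_block)
  bb <- vol$domain$bbox
  geo <- .store_geometry(bb, block_shape)
  # which blocks intersect the domain: walk the interval runs
  present <- logical(geo$total)
  iv <- vol$domain$ivs
  bi_p <- (iv[, "p"] - bb[3]) %/% block_shape[3]
  bi_l <- (iv[, "l"] - bb[2]) %/% block_shape[2]
  b_k1 <- (iv[, "k1"] - bb[1]) %/% block_shape[1]
  b_k2 <- (iv[, "k2"] - bb[1]) %/% block_shape[1]
  for (r in seq_len(nrow(iv))) {
    ids <- 1 + (b_k1[r]:b_k2[r]) +
      geo$nblocks[1] * (bi_l[r] + geo$nblocks[2] * bi_p[r])
    present[ids] <- TRUE
  }
  lut <- integer(geo$total)
  lut[present] <- seq_len(sum(present))
  con <- file(path, "wb")
  on.exit(close(con))
  .write_store_header(con, vol, bb, block_shape, fs_block, lut)
  ki <- kind_info(vol$kind)
  for (id in which(present)) {
    blk <- .extract_block(vol$values, bb, block_shape, geo$nblocks, id,
                          ki$channels, vol$background)
    .write_block(con, blk, vol$kind)
  }
  invisible(path)
}

.write_store_header <- function(con, vol, bb, block_shape, fs_block, lut) {
  iv <- vol$domain$ivs
  writeBin(.STORE_MAGIC, con)
  writeBin(c(1L, .KIND_CODES[[vol$kind]]), con, size = 4, endian = "little")
  writeBin(as.double(rep_len(c(vol$background, 0, 0, 0), 4)), con,
           size = 8, endian = "little")
  writeBin(as.double(vol$voxel_size), con, size = 8, endian = "little")
  writeBin(as.integer(bb), con, size = 4, endian = "little")
  writeBin(as.integer(block_shape), con, size = 4, endian = "little")
  writeBin(as.integer(c(fs_block, nrow(iv), sum(lut > 0))), con,
           size = 4, endian = "little")
  writeBin(as.integer(t(iv[, c("p", "l", "k1", "k2"), drop = FALSE])), con,
           size = 4, endian = "little")
  writeBin(as.integer(lut), con, size = 4, endian = "little")
}

# pull block `id` (1-based, column-major over the block grid) from a dense
# value array, padding partial edge blocks with background
.extract_block <- function(values, bb, bs, nb, id, channels, background) {
  id0 <- id - 1
  bi <- id0 %% nb[1]
  bj <- (id0 %/% nb[1]) %% nb[2]
  bk <- id0 %/% (nb[1] * nb[2])
  dims <- dim(values)[1:3]
  k0 <- bi * bs[1]; l0 <- bj * bs[2]; p0 <- bk * bs[3]
  ks <- (k0 + 1):min(k0 + bs[1], dims[1])
  ls <- (l0 + 1):min(l0 + bs[2], dims[2])
  ps <- (p0 + 1):min(p0 + bs[3], dims[3])
  if (channels == 4L) {
    blk <- array(rep(background, each = prod(bs)), c(bs, 4))
    blk[seq_along(ks), seq_along(ls), seq_along(ps), ] <-
      values[ks, ls, ps, , drop = FALSE]
  } else {
    blk <- array(background[1], bs)
    blk[seq_along(ks), seq_along(ls), seq_along(ps)] <-
      values[ks, ls, ps, drop = FALSE]
  }
  blk
}

.write_block <- function(con, blk, kind) {
  v <- as.vector(if (kind == "rgba") aperm(array(blk, c(prod(dim(blk)[1:3]), 4)),
                                           c(2, 1)) else blk)
  switch(kind,
    u8 = writeBin(as.raw(v), con),
    u16 = writeBin(as.integer(v), con, size = 2, endian = "little"),
    u32 = {
      # R has no unsigned 32-bit: wrap to signed for the on-disk int32
      v <- ifelse(v > 2147483647, v - 4294967296, v)
      writeBin(as.integer(v), con, size = 4, endian = "little")
    },
    f32 = writeBin(as.double(v), con, size = 4, endian = "little"),
    rgba = writeBin(as.raw(v), con))
  invisible(NULL)
}

#' Open a block store for lazy reading
#'
#' Header, interval domain and block lookup table are read eagerly; value
#' blocks are fetched from disk on demand and cached, so a section read
#' touches only the blocks its plane intersects. The returned object supports
#' the same `value_at()` / [cut_section()] interfaces as an in-memory volume.
#'
#' @param path A file written by [write_store()] or [convert_to_store()].
#' @return A lazy `voxvol` (`values` is `NULL`, `lazy` holds the store state).
#' @export
open_store <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", length(.STORE_MAGIC))
  if (!identical(magic, .STORE_MAGIC)) {
    stop("not a block store (bad magic at offset 0): ", path, call. = FALSE)
  }
  hdr_i <- readBin(con, "integer", 2, size = 4, endian = "little")
  if (hdr_i[1] != 1L) stop("unsupported store version ", hdr_i[1], call. = FALSE)
  kind <- names(.KIND_CODES)[match(hdr_i[2], .KIND_CODES)]
  if (is.na(kind)) stop("corrupt store header: unknown kind code at offset 12",
                        call. = FALSE)
  background <- readBin(con, "double", 4, size = 8, endian = "little")
  voxel_size <- readBin(con, "double", 3, size = 8, endian = "little")
  bb <- readBin(con, "integer", 6, size = 4, endian = "little")
  bs <- readBin(con, "integer", 3, size = 4, endian = "little")
  tail_i <- readBin(con, "integer", 3, size = 4, endian = "little")
  n_runs <- tail_i[2]
  runs <- matrix(readBin(con, "integer", 4 * n_runs, size = 4,
                         endian = "little"),
                 ncol = 4, byrow = TRUE,
                 dimnames = list(NULL, c("p", "l", "k1", "k2")))
  dom <- new_ivdom(runs[, c("p", "l", "k1", "k2"), drop = FALSE])
  geo <- .store_geometry(bb, bs)
  lut <- readBin(con, "integer", geo$total, size = 4, endian = "little")
  if (length(lut) < geo$total) {
    stop("corrupt store: truncated LUT", call. = FALSE)
  }
  data_offset <- seek(con, NA)
  ki <- kind_info(kind)
  channels <- ki$channels
  background <- background[seq_len(channels)]
  lazy <- new.env(parent = emptyenv())
  lazy$path <- path
  lazy$bbox <- bb
  lazy$block_shape <- bs
  lazy$nblocks <- geo$nblocks
  lazy$lut <- lut
  lazy$data_offset <- data_offset
  lazy$block_bytes <- prod(bs) * ki$bytes
  lazy$cache <- new.env(parent = emptyenv())
  lazy$last_touched <- 0L
  lazy$total_reads <- 0L
  vol <- voxvol(dom, NULL, kind, voxel_size, background)
  vol$lazy <- lazy
  vol
}

#' Blocks touched by the most recent value operation on a lazy store
#'
#' @param vol A lazy `voxvol` from [open_store()].
#' @return List with `last` (distinct blocks the last lookup needed) and
#'   `total_reads` (cumulative disk block fetches, cache misses only).
#' @export
store_block_stats <- function(vol) {
  stopifnot(!is.null(vol$lazy))
  list(last = vol$lazy$last_touched, total_reads = vol$lazy$total_reads)
}

.read_store_block <- function(lazy, id, kind) {
  key <- as.character(id)
  blk <- lazy$cache[[key]]
  if (!is.null(blk)) return(blk)
  slot <- lazy$lut[id]
  ki <- kind_info(kind)
  bs <- lazy$block_shape
  n <- prod(bs)
  if (slot == 0L) {
    blk <- NULL  # absent: background everywhere
  } else {
    con <- file(lazy$path, "rb")
    on.exit(close(con))
    seek(con, lazy$data_offset + (slot - 1) * lazy$block_bytes)
    blk <- switch(kind,
      u8 = array(as.integer(readBin(con, "raw", n)), bs),
      u16 = array(readBin(con, "integer", n, size = 2, signed = FALSE,
                          endian = "little"), bs),
      u32 = {
        v <- readBin(con, "integer", n, size = 4, endian = "little")
        array(ifelse(v < 0, as.double(v) + 4294967296, as.double(v)), bs)
      },
      f32 = array(readBin(con, "double", n, size = 4, endian = "little"),
                  bs),
      rgba = {
        v <- as.integer(readBin(con, "raw", n * 4L))
        array(aperm(array(v, c(4, bs)), c(2, 3, 4, 1)), c(bs, 4))
      })
    lazy$total_reads <- lazy$total_reads + 1L
  }
  lazy$cache[[key]] <- blk
  blk
}

# lazy counterpart of the dense lookup: group queried voxels by block,
# fetch each needed block once, count the distinct blocks touched
.store_values_lookup <- function(vol, k, l, p) {
  lazy <- vol$lazy
  bb <- lazy$bbox
  bs <- lazy$block_shape
  nb <- lazy$nblocks
  ki <- kind_info(vol$kind)
  n <- length(k)
  out <- if (ki$channels == 4L) {
    matrix(rep(vol$background, each = n), ncol = 4)
  } else {
    rep(vol$background[1], n)
  }
  inbb <- k >= bb[1] & k <= bb[4] & l >= bb[2] & l <= bb[5] &
          p >= bb[3] & p <= bb[6]
  if (!any(inbb)) {
    lazy$last_touched <- 0L
    return(out)
  }
  ko <- k[inbb] - bb[1]; lo <- l[inbb] - bb[2]; po <- p[inbb] - bb[3]
  bi <- ko %/% bs[1]; bj <- lo %/% bs[2]; bk <- po %/% bs[3]
  id <- 1 + bi + nb[1] * (bj + nb[2] * bk)
  ids <- unique(id)
  lazy$last_touched <- length(ids)
  vals <- if (ki$channels == 4L) matrix(0, length(ko), 4) else numeric(length(ko))
  for (b in ids) {
    sel <- id == b
    blk <- .read_store_block(lazy, b, vol$kind)
    if (is.null(blk)) {
      if (ki$channels == 4L) {
        vals[sel, ] <- matrix(rep(vol$background, each = sum(sel)), ncol = 4)
      } else {
        vals[sel] <- vol$background[1]
      }
      next
    }
    kk <- ko[sel] %% bs[1] + 1; ll <- lo[sel] %% bs[2] + 1
    pp <- po[sel] %% bs[3] + 1
    idx <- kk + bs[1] * (ll - 1) + bs[1] * bs[2] * (pp - 1)
    if (ki$channels == 4L) {
      stride <- prod(bs)
      for (ch in 1:4) vals[sel, ch] <- blk[idx + (ch - 1) * stride]
    } else {
      vals[sel] <- blk[idx]
    }
  }
  if (ki$channels == 4L) out[inbb, ] <- vals else out[inbb] <- vals
  out
}

#' Load a lazy store fully into memory
#'
#' Materialises the dense value array (over the bounding box) of an opened
#' store, giving a plain in-memory `voxvol`. Intended for desk-scale testing
#' of representation equivalence, not for large volumes.
#'
#' @param vol A lazy `voxvol`.
#' @return An in-memory `voxvol` comparing equal voxelwise.
#' @export
store_to_memory <- function(vol) {
  stopifnot(!is.null(vol$lazy))
  bb <- vol$lazy$bbox
  ext <- c(bb[4] - bb[1] + 1, bb[5] - bb[2] + 1, bb[6] - bb[3] + 1)
  grid <- expand.grid(k = bb[1]:bb[4], l = bb[2]:bb[5], p = bb[3]:bb[6])
  v <- .store_values_lookup(vol, grid$k, grid$l, grid$p)
  ki <- kind_info(vol$kind)
  values <- if (ki$channels == 4L) array(v, c(ext, 4)) else array(v, ext)
  # background outside the domain, exactly as the dense constructor stores it
  inside <- domain_contains(vol$domain, grid$k, grid$l, grid$p)
  if (ki$channels == 4L) {
    for (ch in 1:4) {
      m <- values[, , , ch]
      m[!inside] <- vol$background[ch]
      values[, , , ch] <- m
    }
  } else {
    values[!inside] <- vol$background[1]
  }
  voxvol(vol$domain, values, vol$kind, vol$voxel_size, vol$background)
}
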