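#' Storage and transfer planning
#'
#' Small arithmetic helpers used when planning block stores and archive
#' deployments: how many bytes a volume occupies and how long a full read
#' would take at a given disk rate — the numbers that justify serving
#' sections rather than shipping volumes. All units are binary (1 GiB =
#' 2^30 bytes, 1 MiB = 2^20 bytes).
#'
#' @name storage-planning
NULL

#' Raw value bytes of a volume of given dimensions and kind
#'
#' @param dims Integer extents `(nk, nl, np)`.
#' @param kind Value kind (e.g. `"rgba"` is 4 bytes per voxel).
#' @return Bytes as a double (counts can exceed 2^31).
#' @export
estimate_volume_bytes <- function(dims, kind = "u8") {
  stopifnot(length(dims) == 3L, all(dims >= 1))
  prod(as.numeric(dims)) * kind_bytes(kind)
}

#' Convert bytes to GiB
#' @param bytes Numeric byte count.
#' @export
bytes_to_gib <- function(bytes) bytes / 2^30

#' Time to read a byte volume at a sustained rate
#'
#' @param bytes Byte count (or use `gib`).
#' @param rate_mib_s Sustained transfer rate in MiB/s.
#' @param gib Alternative input in GiB.
#' @return Seconds.
#' @export
estimate_read_seconds <- function(bytes = NULL, rate_mib_s = 40,
                                  gib = NULL) {
  if (is.null(bytes)) bytes <- gib * 2^30
  bytes / (rate_mib_s * 2^20)
}

#' Plan a block store for a volume of given size
#'
#' @param dims Integer extents `(nk, nl, np)`.
#' @param kind Value kind.
#' @param block_shape Block extents; default [default_block_shape()].
#' @return List with `value_bytes`, `value_gib`, `block_bytes`, `lut_entries`
#'   (block grid size), and `read_seconds_40mib` (full sequential read at
#'   40 MiB/s).
#' @export
store_plan <- function(dims, kind = "u8", block_shape = NULL) {
  if (is.null(block_shape)) block_shape <- default_block_shape(kind)
  .check_block_shape(block_shape, kind)
  vb <- estimate_volume_bytes(dims, kind)
  nb <- ceiling(dims / block_shape)
  list(value_bytes = vb,
       value_gib = bytes_to_gib(vb),
       block_bytes = prod(block_shape) * kind_bytes(kind),
       lut_entries = prod(nb),
       read_seconds_40mib = estimate_read_seconds(vb))
}
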