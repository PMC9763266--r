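#' Volume and sinogram containers on disk
#'
#' The native container is a directory holding `data.bin` (the array as
#' IEEE double, little-endian, column-major in the in-memory axis order)
#' and `meta.json` (shape, axis, voxel size or angles/pitch, and an
#' append-only provenance log). The round trip is bit-exact. TIFF stacks
#' ([export_tiff_stack()]) are the interoperability escape hatch for other
#' tools, and externally reconstructed volumes can be imported by writing
#' this container.
#'
#' @param vol A [hyperspectral_volume()].
#' @param path Container directory (created if missing).
#' @param provenance Optional character note appended to the provenance
#'   log (never overwritten).
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a [hyperspectral_volume()].
#' @export
write_volume <- function(vol, path, provenance = NULL) {
  stopifnot(inherits(vol, "hyperspectral_volume"))
  meta <- list(
    kind = "hyperspectral_volume",
    shape = dim(vol$data),
    axis = list(n_channels = vol$axis$n_channels, gain = vol$axis$gain,
                offset = vol$axis$offset),
    voxel_size_um = vol$voxel_size_um
  )
  write_container(path, vol$data, meta, provenance)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  r <- read_container(path, "hyperspectral_volume")
  ax <- energy_axis(r$meta$axis$n_channels, r$meta$axis$gain,
                    r$meta$axis$offset)
  hyperspectral_volume(r$data, ax, r$meta$voxel_size_um)
}

#' @rdname write_volume
#' @param sino A [spectral_sinogram()].
#' @export
write_sinogram <- function(sino, path, provenance = NULL) {
  stopifnot(inherits(sino, "spectral_sinogram"))
  meta <- list(
    kind = "spectral_sinogram",
    shape = dim(sino$data),
    axis = list(n_channels = sino$axis$n_channels, gain = sino$axis$gain,
                offset = sino$axis$offset),
    angles_deg = sino$angles_deg, pitch_mm = sino$pitch_mm, mode = sino$mode
  )
  write_container(path, sino$data, meta, provenance)
}

#' @rdname write_volume
#' @export
read_sinogram <- function(path) {
  r <- read_container(path, "spectral_sinogram")
  ax <- energy_axis(r$meta$axis$n_channels, r$meta$axis$gain,
                    r$meta$axis$offset)
  spectral_sinogram(r$data, r$meta$angles_deg, r$meta$pitch_mm, ax,
                    mode = r$meta$mode)
}

write_container <- function(path, data, meta, provenance) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta_path <- file.path(path, "meta.json")
  prov <- character(0)
  if (file.exists(meta_path)) {
    old <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    prov <- old$provenance
  }
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  prov <- c(prov,
            sprintf("[%s] written by kedge %s", stamp,
                    as.character(utils::packageVersion("kedge"))),
            if (!is.null(provenance)) sprintf("[%s] %s", stamp, provenance))
  meta$provenance <- as.list(prov)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(data), con, size = 8, endian = "little")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_container <- function(path, expected_kind) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not a kedge container (missing meta.json): ", path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("kind", "shape", "axis")) {
    if (is.null(meta[[field]])) {
      stop("container schema violation: missing field '", field, "' in ", path)
    }
  }
  if (!identical(meta$kind, expected_kind)) {
    stop(sprintf("container at %s holds a %s, expected a %s",
                 path, meta$kind, expected_kind))
  }
  shape <- as.integer(meta$shape)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = prod(shape), size = 8,
                  endian = "little")
  if (length(vals) != prod(shape)) {
    stop("container data.bin truncated: ", path)
  }
  list(data = array(vals, dim = shape), meta = meta)
}

#' Export slices or channels as a TIFF stack
#'
#' Writes 32-bit float TIFF images, one file per z slice (for a 3D map) or
#' per energy channel of a chosen slice (for a volume), for viewing in
#' external tools. Requires the `tiff` package.
#'
#' @param x A [hyperspectral_volume()], `concentration_volume`, or 3D
#'   array.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @param z For a hyperspectral volume: the z slice whose channels are
#'   exported.
#' @return Invisibly, the written file paths.
#' @export
export_tiff_stack <- function(x, dir, prefix = "slice", z = 1L) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- if (inherits(x, "hyperspectral_volume")) {
    aperm(x$data[z, , , , drop = FALSE][1, , , ], c(3, 1, 2))  # (E, y, x)
  } else if (inherits(x, "concentration_volume")) {
    x$concentration
  } else if (is.array(x) && length(dim(x)) == 3L) {
    x
  } else stop("cannot export this object as a TIFF stack")
  n <- dim(arr)[1]
  paths <- character(n)
  for (i in seq_len(n)) {
    img <- arr[i, , ]
    rng <- range(img)
    if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng) else img <- img * 0
    paths[i] <- file.path(dir, sprintf("%s_%04d.tif", prefix, i))
    tiff::writeTIFF(img, paths[i], bits.per.sample = 32L)
  }
  invisible(paths)
}

#' Export a tibble as CSV
#'
#' Thin wrapper used by the CLI for calibration curves, histograms and
#' overlap reports.
#'
#' @param x A data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
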