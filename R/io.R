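#' Read a 3D volume from disk
#'
#' Supported containers: multi-page TIFF (`.tif`/`.tiff`; pages become the
#' first axis), NIfTI-1 (`.nii`/`.nii.gz`), and R's own serialized arrays
#' (`.rds`).  Axis convention: `(depth, lateral, B-scan index)` — a
#' TIFF stack of 32 pages of 64 x 64 yields a volume of shape
#' `(32, 64, 64)`.  2D inputs are rejected with guidance to stack them.
#'
#' @param path file path with a recognized extension.
#' @return numeric 3D array.
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  vol <- switch(ext,
    tif = ,
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
      if (!is.list(pages)) pages <- list(pages)
      if (length(pages) == 1L)
        stop("input is a 2D image; stack B-scans into a 3D volume first")
      d2 <- dim(pages[[1]])
      a <- array(0, c(length(pages), d2[1], d2[2]))
      for (i in seq_along(pages)) a[i, , ] <- pages[[i]]
      sc <- read_tiff_scale(path)
      a * sc$scale + sc$offset
    },
    nii = {
      a <- RNifti::readNifti(path)
      array(as.numeric(a), dim(a))
    },
    rds = readRDS(path),
    stop("unrecognized volume format: .", ext)
  )
  if (length(dim(vol)) == 2L)
    stop("input is a 2D image; stack B-scans into a 3D volume first")
  if (length(dim(vol)) != 3L) stop("expected a 3D volume")
  vol
}

#' Write a 3D volume to disk
#'
#' Inverse of [read_volume()]; the format follows the file extension.
#' TIFF volumes are written as 32-bit float pages (first axis = page), so
#' float32 data round-trip losslessly; values are scaled into `[0, 1]`
#' for the TIFF container and the scale factor is recorded in the
#' file via an accompanying `.scale.json` sidecar when needed.  NIfTI uses
#' single-precision float; `.rds` is bit-exact for doubles.
#'
#' @param volume numeric 3D array.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (length(dim(volume)) != 3L) stop("`volume` must be a 3D array")
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
    tif = ,
    tiff = {
      lo <- min(volume)
      sc <- max(volume) - lo
      if (sc == 0) sc <- 1
      pages <- lapply(seq_len(dim(volume)[1]), function(i) {
        m <- (volume[i, , ] - lo) / sc
        storage.mode(m) <- "double"
        m
      })
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
      jsonlite::write_json(list(offset = lo, scale = sc),
                           paste0(path, ".scale.json"), auto_unbox = TRUE)
    },
    nii = RNifti::writeNifti(RNifti::asNifti(volume), path,
                             datatype = "float"),
    rds = saveRDS(volume, path),
    stop("unrecognized volume format: .", ext)
  )
  invisible(path)
}

# read the sidecar affine (TIFF only)
read_tiff_scale <- function(path) {
  sj <- paste0(path, ".scale.json")
  if (file.exists(sj)) jsonlite::read_json(sj) else list(offset = 0, scale = 1)
}

#' Serialize a complex pyramid to a directory
#'
#' Writes each subband (and the low-pass residuals) as an `.rds` array
#' together with a JSON manifest recording scales, orientations and
#' extents, so pyramids can be inspected or post-processed out of session.
#'
#' @param pyramid a `complex_pyramid`.
#' @param dir destination directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pyramid <- function(pyramid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(levels = pyramid$levels, dims = pyramid$dims,
                   pad_dims = pyramid$pad_dims, subbands = list())
  for (j in seq_len(pyramid$levels)) for (o in 1:28) {
    fn <- sprintf("scale%d_orient%02d.rds", j, o)
    saveRDS(pyramid$subbands[[j]][[o]], file.path(dir, fn))
    manifest$subbands[[length(manifest$subbands) + 1]] <-
      list(scale = j, orientation = o, file = fn,
           extent = dim(pyramid$subbands[[j]][[o]]))
  }
  saveRDS(pyramid$lowpass_trees, file.path(dir, "lowpass_trees.rds"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a serialized pyramid
#'
#' @param dir directory written by [write_pyramid()].
#' @return a `complex_pyramid`.
#' @export
read_pyramid <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  J <- manifest$levels
  subbands <- lapply(seq_len(J), function(j) vector("list", 28))
  for (i in seq_len(nrow(manifest$subbands))) {
    row <- manifest$subbands[i, ]
    subbands[[row$scale]][[row$orientation]] <-
      readRDS(file.path(dir, row$file))
  }
  lows <- readRDS(file.path(dir, "lowpass_trees.rds"))
  structure(list(levels = J, subbands = subbands,
                 lowpass = Reduce(`+`, lows) / 8, lowpass_trees = lows,
                 dims = manifest$dims, pad_dims = manifest$pad_dims),
            class = "complex_pyramid")
}

#' Box-shaped ROI mask helper
#'
#' Builds a logical mask from inclusive index ranges, the configuration
#' counterpart of hand-drawn ROIs.
#'
#' @param dims volume extents.
#' @param from,to inclusive lower/upper corner index 3-vectors.
#' @return logical array mask.
#' @export
roi_box <- function(dims, from, to) {
  m <- array(FALSE, dims)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  m
}
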