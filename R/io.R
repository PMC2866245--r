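#' Read a grayscale image or image stack
#'
#' Reads 2D PNG/TIFF or multi-page TIFF (3D stack); 8/14/16-bit integer or
#' float pixels are accepted and intensities are normalized on load so the
#' maximum equals 1. Multi-channel images are converted to grayscale by
#' channel averaging. All frames of a stack must share dimensions.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`) or a character vector of
#'   frame paths assembled into a stack.
#' @return Normalized 2D matrix or 3D array.
#' @export
read_image_volume <- function(path) {
  read_one <- function(p) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    ext <- tolower(tools::file_ext(p))
    pages <- switch(ext,
      png = list(png::readPNG(p)),
      tif = ,
      tiff = tiff::readTIFF(p, all = TRUE),
      stop("unsupported image format: .", ext, call. = FALSE)
    )
    lapply(pages, function(pg) {
      if (length(dim(pg)) == 3L) pg <- apply(pg, c(1, 2), mean)
      pg
    })
  }
  pages <- unlist(lapply(path, read_one), recursive = FALSE)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) {
    stop("all frames of a stack must share dimensions", call. = FALSE)
  }
  img <- if (length(pages) == 1L) {
    pages[[1L]]
  } else {
    array(unlist(pages), dim = c(dims[[1L]], length(pages)))
  }
  normalize_image(img)
}

#' Write a label map as 16-bit TIFF or 8-bit PNG
#'
#' TIFF labels are stored in the 16-bit integer range (value = label id, so
#' up to 65535 segments); a 3D label array becomes a multi-page TIFF. PNG
#' output is 8-bit (up to 255 segments, 2D only). Label 0 is reserved for
#' "unassigned" and is never produced by a successful run.
#'
#' @param labels Integer label array (2D or 3D).
#' @param path Output path; format chosen by extension (`.tif`/`.tiff`,
#'   or `.png` for 2D).
#' @export
write_label_image <- function(labels, path) {
  stopifnot(max(labels) <= 65535L, min(labels) >= 0L)
  ext <- tolower(tools::file_ext(path))
  scaled <- labels / 65535
  if (ext == "png") {
    if (length(dim(labels)) != 2L) {
      stop("PNG output supports 2D label maps only", call. = FALSE)
    }
    if (max(labels) > 255L) {
      stop("PNG label maps support at most 255 segments", call. = FALSE)
    }
    png::writePNG(labels / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- if (length(dim(labels)) == 3L) {
      lapply(seq_len(dim(labels)[3L]), function(t) scaled[, , t])
    } else {
      list(scaled)
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    stop("unsupported label format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a label map written by [write_label_image()]
#'
#' @param path Path to a label TIFF/PNG.
#' @return Integer label array (2D or 3D).
#' @export
read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pages <- switch(ext,
    png = list(png::readPNG(path)),
    tif = ,
    tiff = tiff::readTIFF(path, all = TRUE),
    stop("unsupported label format: .", ext, call. = FALSE)
  )
  depth <- if (ext == "png") 255 else 65535
  pages <- lapply(pages, function(pg) {
    matrix(as.integer(round(pg * depth)), nrow(pg), ncol(pg))
  })
  if (length(pages) == 1L) {
    pages[[1L]]
  } else {
    array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  }
}

#' Write per-level diagnostics and parameters as JSON
#'
#' @param result A `swa_segmentation`.
#' @param path Output JSON path.
#' @export
write_diagnostics <- function(result, path) {
  stopifnot(inherits(result, "swa_segmentation"))
  segs <- result$segments
  segs$features <- NULL
  jsonlite::write_json(
    list(
      params = unclass(result$params),
      dims = result$dims,
      levels = result$levels,
      segments = segs
    ),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  invisible(path)
}

#' Per-frame tracking report for a space-time segmentation
#'
#' Summarizes each segment ("object tunnel") of a 3D result frame by frame:
#' pixel count, centroid, bounding box, and first/last frame of presence.
#' Frames where a segment is absent are reported with zero pixels and NA
#' geometry.
#'
#' @param result A `swa_segmentation` of a 3D stack.
#' @return Data frame with one row per segment and frame: `segment`,
#'   `frame`, `n_pixels`, `centroid_y`, `centroid_x`, `ymin`, `ymax`,
#'   `xmin`, `xmax`, `first_frame`, `last_frame`.
#' @export
tunnel_report <- function(result) {
  stopifnot(inherits(result, "swa_segmentation"))
  if (length(result$dims) != 3L) {
    stop("tunnel_report requires a 3D (space-time) segmentation",
         call. = FALSE)
  }
  nt <- result$dims[3L]
  ids <- result$segments$id
  rows <- list()
  present <- matrix(FALSE, length(ids), nt)
  for (t in seq_len(nt)) {
    fr <- result$labels[, , t]
    for (s in seq_along(ids)) {
      w <- which(fr == ids[s], arr.ind = TRUE)
      present[s, t] <- nrow(w) > 0
      rows[[length(rows) + 1L]] <- data.frame(
        segment = ids[s], frame = t, n_pixels = nrow(w),
        centroid_y = if (nrow(w)) mean(w[, 1]) else NA_real_,
        centroid_x = if (nrow(w)) mean(w[, 2]) else NA_real_,
        ymin = if (nrow(w)) min(w[, 1]) else NA_integer_,
        ymax = if (nrow(w)) max(w[, 1]) else NA_integer_,
        xmin = if (nrow(w)) min(w[, 2]) else NA_integer_,
        xmax = if (nrow(w)) max(w[, 2]) else NA_integer_
      )
    }
  }
  out <- do.call(rbind, rows)
  first <- apply(present, 1L, function(p) if (any(p)) min(which(p)) else NA)
  last <- apply(present, 1L, function(p) if (any(p)) max(which(p)) else NA)
  out$first_frame <- first[match(out$segment, ids)]
  out$last_frame <- last[match(out$segment, ids)]
  out[order(out$segment, out$frame), ]
}
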