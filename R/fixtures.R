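## Seeded synthetic images with exact ground-truth masks, emulating the
## structures bright-field segmentation must handle: uniform shapes on a
## uniform background, equal-mean/different-variance texture pairs, and
## moving or dividing blobs across frames. Every generator returns
## list(image, mask) where mask is the integer ground-truth labeling
## (1 = background, 2.. = objects).

## Centered square footprint: rows/cols of a k x k block in an n x n image.
centered_block <- function(n, k) {
  off <- floor((n - k) / 2)
  seq(off + 1L, off + k)
}

#' Uniform square on a uniform background
#'
#' An `n x n` image of constant background intensity `bg` with a centered
#' `k x k` block at foreground intensity `fg`: the canonical shape for
#' reasoning about block boundary length (`4k` boundary edges) and area
#' (`2k(k-1)` internal edges) under 4-connectivity.
#'
#' @param n Image side length.
#' @param k Block side length, `k < n`.
#' @param fg,bg Foreground and background intensities in `[0, 1]`.
#' @return `list(image, mask)`; mask is 1 on background, 2 on the block.
#' @examples
#' fx <- make_uniform_square(9, 3)
#' @export
make_uniform_square <- function(n, k, fg = 1, bg = 0) {
  stopifnot(k < n, k >= 1)
  img <- matrix(bg, n, n)
  sel <- centered_block(n, k)
  img[sel, sel] <- fg
  mask <- matrix(1L, n, n)
  mask[sel, sel] <- 2L
  list(image = img, mask = mask)
}

#' Equal-mean, different-variance texture pair
#'
#' A centered `k x k` checkerboard region oscillating `mean +/- amp` on a
#' constant background at `mean`. For even `k` the region mean equals the
#' background mean exactly, so the two regions are indistinguishable by
#' average intensity and differ only in intensity variance (`amp^2` against
#' 0) -- the configuration that separates texture-aware from intensity-only
#' segmentation.
#'
#' @param n Image side length.
#' @param k Texture-region side length (even `k` gives exact mean equality).
#' @param mean Common mean intensity.
#' @param amp Checkerboard amplitude, `amp <= min(mean, 1 - mean)`. The
#'   default full-contrast board (`0.5 +/- 0.5`) gives the maximal variance
#'   contrast (0.25 against 0) and is normalization-neutral (maximum already
#'   1); a single-pixel checkerboard is spatially uncorrelated, so weaker
#'   amplitudes produce textures too incoherent for any affinity-based
#'   grouping to hold together.
#' @return `list(image, mask)`; mask is 1 on background, 2 on the textured
#'   region.
#' @export
make_two_texture <- function(n, k, mean = 0.5, amp = 0.5) {
  stopifnot(k < n, amp >= 0, amp <= min(mean, 1 - mean))
  img <- matrix(mean, n, n)
  sel <- centered_block(n, k)
  parity <- outer(sel, sel, function(y, x) (y + x) %% 2L)
  img[sel, sel] <- mean + amp * ifelse(parity == 0L, 1, -1)
  mask <- matrix(1L, n, n)
  mask[sel, sel] <- 2L
  list(image = img, mask = mask)
}

disk_mask <- function(n, center, radius) {
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  (yy - center[1])^2 + (xx - center[2])^2 <= radius^2
}

#' Moving (optionally dividing) blob across frames
#'
#' A stack of `nt` frames, each with a disk of intensity `fg` on background
#' `bg`, centered along `path` (an `nt x 2` matrix of (y, x) centers). In the
#' imaging regime emulated here the motion between consecutive frames is
#' small compared with the blob, so the blob overlaps itself frame to frame
#' (the default path keeps the intersection-over-union of consecutive masks
#' above 1/3) and its trajectory forms a connected "object tunnel" in
#' space-time. With
#' `split_frame` set, the blob divides at that frame: from there on two disks
#' diverge from the path by `+/- split_step` per elapsed frame along
#' `split_dir`.
#'
#' @param n Frame side length.
#' @param nt Number of frames.
#' @param path `nt x 2` matrix of disk centers (y, x); defaults to a slow
#'   diagonal drift across the frame.
#' @param radius Disk radius in pixels.
#' @param fg,bg Foreground and background intensities.
#' @param noise_sd Standard deviation of optional additive Gaussian noise
#'   (clamped back into `[0, 1]`); default 0.
#' @param seed RNG seed for the noise; ignored when `noise_sd = 0`.
#' @param split_frame Frame at which the blob divides (`NULL` = no division).
#' @param split_dir Unit-ish (y, x) direction of divergence for the two
#'   daughters.
#' @param split_step Per-frame separation step of each daughter, in pixels.
#' @return `list(image, mask, path)`; mask labels are 1 background, 2 blob
#'   (and 3 for the second daughter after `split_frame`).
#' @export
make_moving_blob <- function(n = 60, nt = 5, path = NULL, radius = 10,
                             fg = 0.9, bg = 0.2, noise_sd = 0, seed = 1L,
                             split_frame = NULL, split_dir = c(0, 1),
                             split_step = 3) {
  if (is.null(path)) {
    path <- cbind(
      seq(n / 3, 2 * n / 3, length.out = nt),
      seq(n / 3, 2 * n / 3, length.out = nt)
    )
  }
  path <- matrix(path, ncol = 2)
  stopifnot(nrow(path) == nt, radius >= 1)
  if (any(path[, 1] - radius < 1 | path[, 1] + radius > n |
          path[, 2] - radius < 1 | path[, 2] + radius > n)) {
    stop("blob path leaves the frame", call. = FALSE)
  }
  img <- array(bg, dim = c(n, n, nt))
  mask <- array(1L, dim = c(n, n, nt))
  for (t in seq_len(nt)) {
    if (!is.null(split_frame) && t >= split_frame) {
      sep <- split_step * (t - split_frame + 1)
      d1 <- disk_mask(n, path[t, ] + sep * split_dir, radius)
      d2 <- disk_mask(n, path[t, ] - sep * split_dir, radius)
      fr <- img[, , t]; mk <- mask[, , t]
      fr[d1 | d2] <- fg
      mk[d1] <- 2L
      mk[d2 & !d1] <- 3L
      img[, , t] <- fr; mask[, , t] <- mk
    } else {
      d <- disk_mask(n, path[t, ], radius)
      fr <- img[, , t]; mk <- mask[, , t]
      fr[d] <- fg
      mk[d] <- 2L
      img[, , t] <- fr; mask[, , t] <- mk
    }
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
    img <- pmin(pmax(img, 0), 1)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  list(image = img, mask = mask, path = path)
}
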