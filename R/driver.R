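#' Segmentation parameter set
#'
#' Bundles the eight tuning parameters of the multilevel aggregation
#' algorithm plus implementation switches. The defaults are the recommended
#' starting point for bright-field cell images:
#' `(alpha, alpha_tilde, beta, theta, gamma, d1, sigma, rho) =
#' (100, 100, 100, 0.1, 0.1, 0.15, 5, 1)`. For space-time stacks the
#' `"space_time"` preset lowers `theta` to 0.03, because voxels have more
#' neighbours and strength is measured relative to row sums.
#'
#' @param alpha Finest-level intensity scaling factor (contrast); >= 0.
#' @param alpha_tilde Coarse-level mean-intensity rescaling factor; >= 0.
#' @param beta Coarse-level variance (texture) rescaling factor; >= 0.
#' @param theta Coarsening strength threshold in `[0, 1]`.
#' @param gamma Saliency threshold: a block with saliency below `gamma`
#'   becomes a final segment.
#' @param d1 Sharpening threshold in `[0, 0.5)`: memberships above `1 - d1`
#'   become 1, below `d1` become 0.
#' @param sigma Detection threshold level: salient blocks only on levels
#'   `> sigma` (avoids small segments).
#' @param rho Variance threshold level: texture rescaling only on levels
#'   `> rho` (variance of small blocks is uninformative).
#' @param use_variance Include the multilevel variance features? Disabling
#'   reproduces intensity-only segmentation.
#' @param measure Saliency measure: `"scale_invariant"` (default) or
#'   `"original"`.
#' @param feature_metric Distance between feature vectors for the `beta`
#'   rescaling: `"l1"` (default) or `"l2"`.
#' @param alpha_temporal Optional separate scaling factor for temporal edges
#'   of a 3D stack; `NULL` means equal to `alpha`.
#' @param max_levels Safety cap on the number of levels.
#' @param preset `"default"` or `"space_time"`; a preset only fills values
#'   you do not set explicitly.
#' @return Object of class `swa_params`.
#' @examples
#' swa_params()
#' swa_params(preset = "space_time")
#' @export
swa_params <- function(alpha = 100, alpha_tilde = 100, beta = 100,
                       theta = NULL, gamma = 0.1, d1 = 0.15,
                       sigma = 5, rho = 1,
                       use_variance = TRUE,
                       measure = c("scale_invariant", "original"),
                       feature_metric = c("l1", "l2"),
                       alpha_temporal = NULL,
                       max_levels = 25,
                       preset = c("default", "space_time")) {
  preset <- match.arg(preset)
  if (is.null(theta)) {
    theta <- if (preset == "space_time") 0.03 else 0.1
  }
  measure <- match.arg(measure)
  feature_metric <- match.arg(feature_metric)
  stopifnot(
    alpha >= 0, alpha_tilde >= 0, beta >= 0,
    theta >= 0, theta <= 1, gamma >= 0,
    d1 >= 0, d1 < 0.5,
    sigma >= 1, rho >= 1, max_levels >= 2
  )
  structure(
    list(
      alpha = alpha, alpha_tilde = alpha_tilde, beta = beta,
      theta = theta, gamma = gamma, d1 = d1,
      sigma = as.integer(sigma), rho = as.integer(rho),
      use_variance = isTRUE(use_variance),
      measure = measure, feature_metric = feature_metric,
      alpha_temporal = alpha_temporal,
      max_levels = as.integer(max_levels)
    ),
    class = "swa_params"
  )
}

#' @export
print.swa_params <- function(x, ...) {
  cat(sprintf(
    paste0("<swa_params> alpha=%g alpha_tilde=%g beta=%g theta=%g gamma=%g ",
           "d1=%g sigma=%d rho=%d\n  measure=%s variance=%s metric=%s\n"),
    x$alpha, x$alpha_tilde, x$beta, x$theta, x$gamma, x$d1, x$sigma, x$rho,
    x$measure, x$use_variance, x$feature_metric
  ))
  invisible(x)
}

#' Sharpen a membership matrix
#'
#' One step of the bottom-up de-overlapping: in each row (node), memberships
#' of at least `1 - d1` are set to 1 with the rest of the row zeroed;
#' memberships of at most `d1` are zeroed; surviving rows are renormalized to
#' sum 1. A row whose entries were all at most `d1` keeps only its maximal
#' entry (set to 1; earliest segment on ties).
#'
#' @param U Nonnegative node-by-segment membership matrix with unit row sums.
#' @param d1 Sharpening threshold in `[0, 0.5)`.
#' @return Sharpened row-stochastic matrix of the same shape.
#' @export
sharpen <- function(U, d1) {
  stopifnot(d1 >= 0, d1 < 0.5)
  U <- as.matrix(U)
  if (ncol(U) == 1L) {
    return(matrix(1, nrow(U), 1L))
  }
  jmax <- max.col(U, ties.method = "first")
  # rows dominated by one segment: assign fully (at most one entry >= 1 - d1
  # since d1 < 0.5 and rows sum to 1)
  hi <- U >= 1 - d1
  rows_hi <- which(rowSums(hi) > 0)
  if (length(rows_hi)) {
    U[rows_hi, ] <- 0
    U[cbind(rows_hi, jmax[rows_hi])] <- 1
  }
  rest <- setdiff(seq_len(nrow(U)), rows_hi)
  if (length(rest)) {
    Ur <- U[rest, , drop = FALSE]
    Ur[Ur <= d1] <- 0
    rs <- rowSums(Ur)
    dead <- rs == 0
    if (any(dead)) {
      Ur[dead, ] <- 0
      Ur[cbind(which(dead), jmax[rest][dead])] <- 1
      rs[dead] <- 1
    }
    U[rest, ] <- Ur / rs
  }
  U
}

#' Assign each node to the segment it belongs to most
#'
#' Per-row argmax of the membership matrix; ties go to the lowest segment id.
#'
#' @param U Membership matrix with unit row sums.
#' @return Integer vector of segment ids, one per node.
#' @export
assign_labels <- function(U) {
  U <- as.matrix(U)
  if (ncol(U) == 1L) return(rep(1L, nrow(U)))
  max.col(U, ties.method = "first")
}

## Append detection records (and mark graph$detection) for nodes flagged on
## this level, in increasing node order; `values` may be NA for fallback.
record_detections <- function(state, nodes, values) {
  g <- state$graph
  for (idx in nodes) {
    state$records[[length(state$records) + 1L]] <- list(
      level = g$level,
      node = idx,
      saliency = values[idx],
      mean_intensity = g$intensity[idx],
      features = as.numeric(g$features[idx, ])
    )
    g$detection[idx] <- length(state$records)
  }
  state$graph <- g
  state
}

#' Segment an image or space-time stack by multilevel aggregation
#'
#' Runs one V-cycle. Top-down: the pixel affinity graph is recursively
#' coarsened (Ruge-Stuben first-pass C/F splitting, interpolation, Galerkin
#' triple products for `A`, `G`, `V`, coarse mean intensities and variance
#' features, intensity and texture rescalings), and on each level beyond
#' `sigma` blocks whose saliency falls below `gamma` are frozen as final
#' segments and forced through the remaining levels. The top-down phase ends
#' when all blocks are salient (or coarsening stalls, in which case the
#' remaining blocks are declared salient with a warning). Bottom-up: the
#' segments' fractional memberships are interpolated back level by level,
#' sharpened with threshold `d1`, and finally each pixel takes the segment it
#' belongs to most.
#'
#' @param img 2D matrix or 3D array of intensities (normalized internally so
#'   the maximum is 1).
#' @param params A [swa_params()] object.
#' @return Object of class `swa_segmentation`: `labels` (integer array shaped
#'   like `img`; ids 1..K in order of detection), `segments` (per-segment
#'   data frame: detection level, saliency at detection, mean intensity,
#'   feature vector, pixel count), `levels` (per-level diagnostics), `params`
#'   and `dims`.
#' @examples
#' fx <- make_uniform_square(n = 24, k = 8)
#' seg <- swa_segment(fx$image, swa_params(alpha = 20, sigma = 2))
#' table(seg$labels)
#' @export
swa_segment <- function(img, params = swa_params()) {
  stopifnot(inherits(params, "swa_params"))
  img <- normalize_image(img)
  alpha_t <- if (is.null(params$alpha_temporal)) params$alpha else
    params$alpha_temporal
  graph <- build_fine_graph(img, params$alpha, alpha_t)
  dims <- dim(img)

  state <- list(graph = graph, records = list())
  transfers <- list()
  level_diag <- list()
  stall <- 0L

  repeat {
    g <- state$graph
    rep <- detect_salient(g, params$gamma, params$sigma, params$measure)
    state$graph <- rep$graph
    state <- record_detections(state, rep$newly_salient, rep$values)
    level_diag[[length(level_diag) + 1L]] <- data.frame(
      level = state$graph$level,
      n_nodes = n_nodes(state$graph),
      n_salient = sum(state$graph$salient),
      newly_salient = length(rep$newly_salient)
    )
    if (all(state$graph$salient)) break

    fallback <- NULL
    if (state$graph$level >= params$max_levels) {
      fallback <- "maximum number of levels reached"
    }
    split <- NULL
    if (is.null(fallback)) {
      split <- first_pass_cf(state$graph, params$theta)
      if (length(split$c_points) == n_nodes(state$graph)) {
        stall <- stall + 1L
        if (stall >= 2L) fallback <- "coarsening stalled"
      } else {
        stall <- 0L
      }
    }
    if (!is.null(fallback)) {
      warning(sprintf(
        "%s with non-salient blocks remaining; declaring them salient",
        fallback
      ), call. = FALSE)
      remaining <- which(!state$graph$salient)
      state$graph$salient[remaining] <- TRUE
      state <- record_detections(state, remaining,
                                 rep(NA_real_, n_nodes(state$graph)))
      break
    }

    g <- state$graph
    P <- build_interpolation(g, split)
    A2 <- galerkin(g$A, P)
    G2 <- galerkin(g$G, P)
    V2 <- galerkin(g$V, P)
    I2 <- coarse_intensity(P, g$intensity)
    F2 <- coarse_features(P, g$intensity, g$features)
    A2 <- rescale_by_intensity(A2, I2, params$alpha_tilde)
    if (params$use_variance) {
      A2 <- rescale_by_variance(A2, F2, params$beta, g$level + 1L,
                                params$rho, params$feature_metric)
    }
    cp <- split$c_points
    transfers[[g$level]] <- P
    state$graph <- new_level_graph(
      level = g$level + 1L, A = A2, G = G2, V = V2,
      intensity = I2, features = F2,
      salient = g$salient[cp], dims = NULL,
      detection = g$detection[cp]
    )
  }

  ## Bottom-up phase: memberships from the coarsest level down, sharpened on
  ## every level; segment columns ordered by detection (level, node index).
  g <- state$graph
  nseg <- length(state$records)
  stopifnot(nseg == n_nodes(g))  # all coarsest blocks are salient
  U <- matrix(0, nseg, nseg)
  U[cbind(seq_len(nseg), g$detection)] <- 1
  U <- sharpen(U, params$d1)
  if (length(transfers)) {
    for (r in rev(seq_along(transfers))) {
      U <- as.matrix(transfers[[r]] %*% U)
      U <- sharpen(U, params$d1)
    }
  }
  labels <- array(assign_labels(U), dim = dims)

  counts <- tabulate(labels, nbins = nseg)
  segments <- data.frame(
    id = seq_len(nseg),
    level = vapply(state$records, function(r) r$level, integer(1)),
    saliency = vapply(state$records, function(r) as.numeric(r$saliency),
                      numeric(1)),
    mean_intensity = vapply(state$records, function(r) r$mean_intensity,
                            numeric(1)),
    n_pixels = counts
  )
  segments$features <- lapply(state$records, function(r) r$features)

  structure(
    list(
      labels = labels,
      segments = segments,
      levels = do.call(rbind, level_diag),
      params = params,
      dims = dims
    ),
    class = "swa_segmentation"
  )
}

#' @export
print.swa_segmentation <- function(x, ...) {
  cat(sprintf(
    "<swa_segmentation> %s image, %d segment(s), %d level(s)\n",
    paste(x$dims, collapse = "x"), nrow(x$segments), max(x$levels$level)
  ))
  print(x$segments[, c("id", "level", "saliency", "mean_intensity",
                       "n_pixels")])
  invisible(x)
}

#' Merge segments with near-identical feature summaries
#'
#' Optional post-processing: when a non-contiguous background is found as
#' several segments, they can be grouped because their summaries (mean
#' intensity plus variance feature vector, shorter vectors zero-padded) are
#' nearly identical. Segments whose summaries differ by less than `tol` in L1
#' distance are merged transitively into one label; labels are renumbered
#' consecutively, preserving detection order of each group's earliest member.
#'
#' @param result A `swa_segmentation`.
#' @param tol Nonnegative merge tolerance; `tol = 0` changes nothing.
#' @return Updated `swa_segmentation`.
#' @export
merge_background <- function(result, tol) {
  stopifnot(inherits(result, "swa_segmentation"), tol >= 0)
  k <- nrow(result$segments)
  if (tol == 0 || k < 2L) return(result)
  maxlen <- max(vapply(result$segments$features, length, integer(1)))
  summ <- t(vapply(seq_len(k), function(i) {
    f <- result$segments$features[[i]]
    c(result$segments$mean_intensity[i], f, rep(0, maxlen - length(f)))
  }, numeric(1L + maxlen)))
  # union-find over pairs closer than tol
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      if (sum(abs(summ[i, ] - summ[j, ])) < tol) {
        parent[find(j)] <- find(i)
      }
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  newid <- match(root, sort(unique(root)))
  labels <- array(newid[result$labels], dim = result$dims)
  segments <- result$segments[match(sort(unique(root)), root), ]
  segments$id <- seq_len(nrow(segments))
  segments$n_pixels <- tabulate(labels, nbins = nrow(segments))
  segments$merged_from <- lapply(seq_len(nrow(segments)), function(g) {
    which(newid == g)
  })
  result$labels <- labels
  result$segments <- segments
  result
}

#' Pixel accuracy between two label maps
#'
#' Compares a predicted labeling with a ground-truth labeling up to label
#' permutation: labels are matched greedily by overlap (largest confusion
#' entries first, each predicted and each true label used at most once) and
#' the accuracy is the fraction of pixels whose matched labels agree.
#'
#' @param pred,truth Integer arrays of identical shape.
#' @return Accuracy in `[0, 1]`.
#' @export
label_accuracy <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  conf <- table(as.vector(pred), as.vector(truth))
  matched <- 0
  used_r <- logical(nrow(conf))
  used_c <- logical(ncol(conf))
  ord <- order(conf, decreasing = TRUE)
  for (o in ord) {
    r <- (o - 1L) %% nrow(conf) + 1L
    c <- (o - 1L) %/% nrow(conf) + 1L
    if (!used_r[r] && !used_c[c] && conf[o] > 0) {
      matched <- matched + conf[o]
      used_r[r] <- TRUE
      used_c[c] <- TRUE
    }
  }
  matched / length(pred)
}
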