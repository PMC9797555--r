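# Vessel segmentation and morphology: contrast enhancement (2x bilinear
# interpolation, self-guided edge-preserving filter, multiscale Frangi
# vesselness), Otsu binarization, morphological thinning with the
# >2-neighbour branch-point rule, fill fraction, and paired contralateral /
# ipsilateral statistics.

box_mean <- function(mat, radius) {
  k <- matrix(1, 2 * radius + 1, 2 * radius + 1)
  k <- k / sum(k)
  as.matrix(EBImage::filter2(mat, k, boundary = "replicate"))
}

#' Self-guided edge-preserving filter
#'
#' Guided filter with the image as its own guide: smooths low-variance
#' regions while preserving strong edges.
#'
#' @param img Numeric matrix.
#' @param radius Box-window radius (pixels).
#' @param eps Regularisation (on the squared intensity scale).
#' @return Filtered matrix.
#' @export
guided_filter <- function(img, radius = 4, eps = 1e-3) {
  m <- box_mean(img, radius)
  m2 <- box_mean(img * img, radius)
  v <- pmax(m2 - m * m, 0)
  a <- v / (v + eps)
  b <- m - a * m
  box_mean(a, radius) * img + box_mean(b, radius)
}

# Gaussian-derivative Hessian at scale sigma (pixels), scale-normalised.
hessian_at_scale <- function(img, sigma) {
  half <- max(2, ceiling(3 * sigma))
  x <- seq(-half, half)
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  conv <- function(mat, kx, ky) {
    k <- ky %o% kx
    as.matrix(EBImage::filter2(mat, k, boundary = "replicate"))
  }
  s2 <- sigma^2
  list(xx = s2 * conv(img, g2, g), yy = s2 * conv(img, g, g2),
       xy = s2 * conv(img, g1, g1))
}

#' Multiscale Frangi vesselness
#'
#' Hessian-eigenvalue ridge detector for bright curvilinear structures,
#' maximised over scales. Uses the standard blobness and structureness
#' terms with `beta = 0.5` and `c` set to half the maximum Hessian norm
#' per scale.
#'
#' @param img Numeric matrix.
#' @param scales Gaussian scales (pixels).
#' @param beta Blobness sensitivity.
#' @return Vesselness matrix in `[0, 1]` (up to normalisation by its max).
#' @export
frangi_vesselness <- function(img, scales = c(1, 2, 4, 8), beta = 0.5) {
  out <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    H <- hessian_at_scale(img, s)
    tr <- H$xx + H$yy
    disc <- sqrt(pmax((H$xx - H$yy)^2 + 4 * H$xy^2, 0))
    l1 <- (tr + disc) / 2
    l2 <- (tr - disc) / 2
    # order by magnitude: |lam1| <= |lam2|
    swap <- abs(l1) > abs(l2)
    tmp <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- tmp
    S <- sqrt(l1^2 + l2^2)
    cpar <- max(S) / 2
    if (cpar == 0) next
    Rb <- ifelse(l2 != 0, l1 / l2, 0)
    v <- exp(-Rb^2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * cpar^2)))
    v[l2 > 0] <- 0  # bright ridges have a strongly negative principal curvature
    out <- pmax(out, v)
  }
  out
}

#' ROI pre-processing for vessel segmentation
#'
#' Fixed enhancement pipeline: 2-fold bilinear upsampling, self-guided
#' filtering, multiscale Frangi vesselness, min-max normalisation to
#' `[0, 1]`.
#'
#' @param roi Numeric matrix (NA pixels treated as 0).
#' @param scales Frangi scales on the upsampled grid (pixels).
#' @param guide_radius,guide_eps Guided-filter settings.
#' @return Enhanced matrix, `2 x` the input dimensions.
#' @export
preprocess_roi <- function(roi, scales = c(1, 2, 4, 8),
                           guide_radius = 4, guide_eps = 1e-3) {
  if (length(roi) == 0) stop("ROI is empty", call. = FALSE)
  roi[is.na(roi)] <- 0
  up <- as.matrix(EBImage::resize(roi, w = 2 * nrow(roi), h = 2 * ncol(roi)))
  sm <- guided_filter(up, guide_radius, guide_eps)
  v <- frangi_vesselness(sm, scales)
  rng <- range(v)
  if (diff(rng) == 0) return(matrix(0, nrow(v), ncol(v)))
  (v - rng[1]) / diff(rng)
}

#' Otsu binarization of an enhanced image
#'
#' Global Otsu threshold (256 levels on `[0, 1]`); foreground is the
#' high-vesselness class. A constant image yields an empty mask with a
#' warning.
#'
#' @param enhanced Matrix with values in `[0, 1]`.
#' @return Object of class `vessel_mask`: binary `mask` matrix and the
#'   `threshold` used.
#' @export
binarize <- function(enhanced) {
  if (diff(range(enhanced)) == 0) {
    warning("constant image: empty vessel mask", call. = FALSE)
    return(structure(list(mask = matrix(0L, nrow(enhanced), ncol(enhanced)),
                          threshold = NA_real_), class = "vessel_mask"))
  }
  thr <- EBImage::otsu(EBImage::Image(enhanced), range = c(0, 1), levels = 256)
  structure(list(mask = (enhanced > thr) + 0L, threshold = thr),
            class = "vessel_mask")
}

# one Zhang-Suen sub-iteration; returns updated binary matrix
zs_subiter <- function(img, step) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- matrix(0L, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- img
  sh <- function(dr, dc) pad[(2 + dr):(ny + 1 + dr), (2 + dc):(nx + 1 + dc)]
  p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
  p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
  B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  A <- matrix(0L, ny, nx)
  for (i in 1:8) A <- A + (seqs[[i]] == 0 & seqs[[i + 1]] == 1)
  if (step == 1) {
    cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
  } else {
    cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
  }
  del <- img == 1 & B >= 2 & B <= 6 & A == 1 & cond
  img[del] <- 0L
  img
}

# Sequential cleanup of residual staircase doublings: repeatedly delete
# simple points (Yokoi 8-connectivity number 1) with at least two skeleton
# neighbours. Zhang-Suen alone can leave 2-px diagonal staircases on masks
# with rough boundaries.
skeleton_cleanup <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  repeat {
    changed <- FALSE
    fg <- which(img == 1L)
    for (p in fg) {
      r <- ((p - 1L) %% ny) + 1L
      cl <- ((p - 1L) %/% ny) + 1L
      if (r == 1L || r == ny || cl == 1L || cl == nx) next
      # neighbours in cyclic order E, NE, N, NW, W, SW, S, SE
      n <- c(img[r, cl + 1], img[r - 1, cl + 1], img[r - 1, cl],
             img[r - 1, cl - 1], img[r, cl - 1], img[r + 1, cl - 1],
             img[r + 1, cl], img[r + 1, cl + 1])
      if (sum(n) < 2) next
      xb <- 1L - n
      c8 <- 0L
      for (k in c(1L, 3L, 5L, 7L)) {
        k1 <- if (k == 7L) 8L else k + 1L
        k2 <- if (k >= 7L) k - 6L else k + 2L
        c8 <- c8 + (xb[k] - xb[k] * xb[k1] * xb[k2])
      }
      if (c8 == 1L) {
        img[r, cl] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

#' Skeletonize a vessel mask and split it into branches
#'
#' Morphological (Zhang-Suen) thinning to one-pixel centrelines. A branch
#' point is any skeleton pixel with more than two nonzero 8-neighbours on
#' the skeleton; removing the branch points partitions the skeleton into
#' branches (8-connected components). Branches shorter than `prune_px`
#' pixels are pruned before counting to suppress thinning artifacts.
#'
#' @param mask A [binarize()] result or a binary matrix.
#' @param prune_px Minimum branch length kept (pixels).
#' @return Object of class `skeleton_graph`: `skeleton` (binary matrix),
#'   `branch_points` tibble (`row`, `col`), `branch_labels` (integer
#'   matrix), `branch_count`.
#' @export
skeletonize_and_branch <- function(mask, prune_px = 3) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  img <- (m != 0) + 0L
  repeat {
    before <- img
    img <- zs_subiter(img, 1)
    img <- zs_subiter(img, 2)
    if (identical(img, before)) break
  }
  skel <- skeleton_cleanup(img)
  nb <- as.matrix(EBImage::filter2(skel + 0,
                                   matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3),
                                   boundary = 0))
  nb <- round(nb)
  bp <- skel == 1 & nb > 2
  branches_img <- skel
  branches_img[bp] <- 0L
  lab <- label_components(branches_img == 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= prune_px)
  lab[!lab %in% keep] <- 0L
  # relabel compactly
  if (length(keep)) {
    lab <- matrix(match(lab, keep, nomatch = 0L), nrow(lab), ncol(lab))
  }
  idx <- which(bp)
  structure(list(
    skeleton = skel,
    branch_points = tibble::tibble(row = ((idx - 1) %% nrow(skel)) + 1,
                                   col = ((idx - 1) %/% nrow(skel)) + 1),
    branch_labels = lab,
    branch_count = length(keep)
  ), class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton: %d px, %d branch points, %d branches>\n",
              sum(x$skeleton), nrow(x$branch_points), x$branch_count))
  invisible(x)
}

#' Vessel fill fraction
#'
#' Foreground pixel count divided by total pixel count of the mask.
#'
#' @param mask A [binarize()] result or a binary matrix.
#' @return Scalar in `[0, 1]`.
#' @export
fill_fraction <- function(mask) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  mean(m != 0)
}

#' Segment and quantify one intensity ROI
#'
#' Runs the fixed pipeline [preprocess_roi()] -> [binarize()] ->
#' [skeletonize_and_branch()] and reports fill fraction (computed on the
#' upsampled mask) and branch count.
#'
#' @param roi Numeric matrix (an intensity-map ROI; NA allowed).
#' @param ... Passed to [preprocess_roi()] and [skeletonize_and_branch()].
#' @return List: `enhanced`, `mask`, `skeleton`, and a one-row `metrics`
#'   tibble (`fill_fraction`, `branch_count`, `branch_points`).
#' @export
quantify_roi <- function(roi, ...) {
  args <- list(...)
  pre_args <- args[names(args) %in% c("scales", "guide_radius", "guide_eps")]
  sk_args <- args[names(args) %in% "prune_px"]
  enhanced <- do.call(preprocess_roi, c(list(roi), pre_args))
  mask <- binarize(enhanced)
  skel <- do.call(skeletonize_and_branch, c(list(mask), sk_args))
  list(enhanced = enhanced, mask = mask, skeleton = skel,
       metrics = tibble::tibble(
         fill_fraction = fill_fraction(mask),
         branch_count = skel$branch_count,
         branch_points = nrow(skel$branch_points)))
}

#' Paired two-sided t statistics and Cohen's d
#'
#' For paired samples (pairing by index), with differences
#' `d_i = contra_i - ipsi_i`: `t = mean(d) / (sd(d) / sqrt(n))`, two-sided
#' p from Student's t with `n - 1` degrees of freedom, and paired Cohen's
#' `d = mean(d) / sd(d)` (identically `t / sqrt(n)`). A zero-variance
#' difference vector leaves t and d undefined (NA), reported as such.
#'
#' @param values_contra,values_ipsi Equal-length numeric vectors, n >= 2.
#' @return Object of class `paired_stats` with fields `t`, `p_two_sided`,
#'   `cohen_d_paired`, `n`, `df`, `mean_diff`, `sd_diff`.
#' @export
paired_stats <- function(values_contra, values_ipsi) {
  n <- length(values_contra)
  if (length(values_ipsi) != n || n < 2) {
    stop("paired samples require equal lengths with n >= 2", call. = FALSE)
  }
  d <- values_contra - values_ipsi
  sdd <- sd(d)
  if (sdd == 0) {
    out <- list(t = NA_real_, p_two_sided = NA_real_,
                cohen_d_paired = NA_real_, n = n, df = n - 1,
                mean_diff = mean(d), sd_diff = 0, undefined = TRUE)
  } else {
    t <- mean(d) / (sdd / sqrt(n))
    out <- list(t = t, p_two_sided = 2 * pt(-abs(t), df = n - 1),
                cohen_d_paired = mean(d) / sdd, n = n, df = n - 1,
                mean_diff = mean(d), sd_diff = sdd, undefined = FALSE)
  }
  structure(out, class = "paired_stats")
}

#' @export
print.paired_stats <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<paired stats: n = %d, zero-variance differences; t and d undefined>\n", x$n))
  } else {
    cat(sprintf("<paired stats: n = %d, t(%d) = %.4f, p = %.4f, Cohen's d = %.4f>\n",
                x$n, x$df, x$t, x$p_two_sided, x$cohen_d_paired))
  }
  invisible(x)
}

#' @rdname paired_stats
#' @param x A `paired_stats` object.
#' @param ... Unused.
#' @export
tidy.paired_stats <- function(x, ...) {
  tibble::tibble(estimate = x$mean_diff, statistic = x$t,
                 p.value = x$p_two_sided, parameter = x$df,
                 cohen_d = x$cohen_d_paired)
}

#' @rdname paired_stats
#' @export
glance.paired_stats <- function(x, ...) {
  tibble::tibble(n = x$n, statistic = x$t, p.value = x$p_two_sided,
                 cohen_d = x$cohen_d_paired, undefined = x$undefined)
}
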