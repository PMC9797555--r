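# Vessel enhancement, Otsu binarization, skeleton/branch analysis, fill
# fraction and paired statistics.

test_that("enhancement doubles the raster and favours ridges over blobs", {
  set.seed(1)
  img <- matrix(0.05, 60, 60)
  img[29:31, 6:54] <- 1                           # straight bright ridge
  enh <- preprocess_roi(img)
  expect_equal(dim(enh), c(120, 120))
  # vesselness peaks along the ridge centreline
  expect_gt(mean(enh[59:60, 30:90]), 0.5)
  expect_gt(mean(enh[59:60, 30:90]), 3 * mean(enh[80:100, 30:90]))
  # equal-contrast isotropic blob
  blob <- matrix(0.05, 60, 60)
  rr <- outer(1:60, rep(1, 60)); cc <- t(rr)
  blob[(rr - 30)^2 + (cc - 30)^2 <= 9] <- 1
  enh_b <- frangi_vesselness(astivol:::blur_matrix(blob, 1))
  enh_r <- frangi_vesselness(astivol:::blur_matrix(img, 1))
  # at the structure centre, the isotropic blob (lambda1 ~ lambda2) scores
  # far below the equal-contrast ridge; its rim is genuinely curvilinear,
  # so the comparison is taken at the centres
  expect_lt(max(enh_b[29:31, 29:31]), 0.5 * max(enh_r[29:31, 25:35]))
})

test_that("Otsu threshold maximises between-class variance", {
  set.seed(7)
  vals <- c(rnorm(500, 0.2, 0.03), rnorm(500, 0.8, 0.03))
  img <- matrix(pmin(pmax(vals, 0), 1), 25, 40)
  mask <- binarize(img)
  expect_gt(mask$threshold, 0.3)
  expect_lt(mask$threshold, 0.7)
  # brute-force oracle: the between-class variance achieved at the chosen
  # threshold must equal the exhaustive maximum over all 256 bin levels
  # (the empty valley between modes makes the maximiser a flat plateau, so
  # the objective, not the argmax, is the invariant quantity)
  between_class_var <- function(x, thr, levels = 256) {
    bins <- floor(x * levels); bins[bins == levels] <- levels - 1
    p <- tabulate(bins + 1, nbins = levels) / length(x)
    t <- max(1, min(levels - 1, round(thr * levels)))
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(0)
    mu0 <- sum((0:(t - 1)) * p[1:t]) / w0
    mu1 <- sum((t:(levels - 1)) * p[(t + 1):levels]) / w1
    w0 * w1 * (mu0 - mu1)^2
  }
  brute_max <- max(sapply(1:255 / 256, function(t) between_class_var(img, t)))
  expect_equal(between_class_var(img, mask$threshold), brute_max,
               tolerance = 1e-9)
  expect_warning(empty <- binarize(matrix(0.5, 10, 10)), "constant")
  expect_equal(sum(empty$mask), 0)
})

test_that("skeleton branch rule matches neighbour-count enumeration", {
  # straight one-pixel line: one branch, no branch points
  m <- matrix(0L, 15, 15); m[8, 3:13] <- 1L
  s <- skeletonize_and_branch(m)
  expect_equal(s$branch_count, 1)
  expect_equal(nrow(s$branch_points), 0)
  # symmetric Y: the junction pixel has three skeleton neighbours
  y <- matrix(0L, 21, 21)
  y[11:20, 11] <- 1L
  for (k in 0:9) { y[10 - k, 11 - k] <- 1L; y[10 - k, 11 + k] <- 1L }
  s <- skeletonize_and_branch(y)
  expect_equal(nrow(s$branch_points), 1)
  expect_equal(s$branch_count, 3)
  # X of two crossing diagonals: removal of the crossing yields 4 branches
  x <- matrix(0L, 21, 21)
  for (k in -10:10) { x[11 + k, 11 + k] <- 1L; x[11 + k, 11 - k] <- 1L }
  s <- skeletonize_and_branch(x)
  expect_equal(s$branch_count, 4)
  # skeleton is contained in the mask
  expect_true(all(x[s$skeleton == 1L] == 1L))
})

test_that("fill fraction is the foreground pixel share", {
  expect_equal(fill_fraction(matrix(1L, 5, 5)), 1)
  expect_equal(fill_fraction(matrix(0L, 5, 5)), 0)
  m <- matrix(0L, 10, 10); m[1:5, 1:5] <- 1L
  expect_equal(fill_fraction(m), 0.25)
  # monotone under dilation
  set.seed(3)
  m2 <- matrix(rbinom(400, 1, 0.2), 20, 20)
  dil <- as.matrix(EBImage::dilate(m2, EBImage::makeBrush(3, "box")))
  expect_gte(fill_fraction(dil), fill_fraction(m2))
})

test_that("branch count on rendered vessel trees matches generator truth", {
  for (nb in 0:3) {
    ph <- make_vessel_tree(nb, depth_span_um = 300, fov_mm = 1,
                           radius_um = 12, seed = 1)
    img <- phantom_density_map(ph, 180, 180, PX)
    q <- quantify_roi(img)
    expect_equal(q$metrics$branch_count, ph$branch_count)
  }
})

test_that("paired statistics reproduce closed-form values on the worked diffs", {
  contra <- c(4, 6, 9); ipsi <- c(3, 4, 6)  # diffs 1, 2, 3
  ps <- paired_stats(contra, ipsi)
  expect_equal(ps$t, 2 / (1 / sqrt(3)))          # mean 2, SD 1, n 3
  expect_equal(ps$t, 3.4641, tolerance = 1e-3)
  expect_equal(ps$cohen_d_paired, 2)
  # closed-form two-sided tail for df = 2: p = 1 - t / sqrt(t^2 + 2)
  expect_equal(ps$p_two_sided, 1 - ps$t / sqrt(ps$t^2 + 2), tolerance = 1e-12)
  expect_equal(ps$p_two_sided, 0.0742, tolerance = 1e-3)
  # independent oracle: stats::t.test
  tt <- t.test(contra, ipsi, paired = TRUE)
  expect_equal(ps$t, unname(tt$statistic))
  expect_equal(ps$p_two_sided, tt$p.value)
  expect_equal(ps$df, unname(tt$parameter))
})

test_that("Cohen's d equals t over sqrt(n) for arbitrary paired samples", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    a <- rnorm(n, 1); b <- rnorm(n)
    ps <- paired_stats(a, b)
    expect_equal(ps$cohen_d_paired, ps$t / sqrt(ps$n), tolerance = 1e-12)
  }
  # identical pairs: undefined, not zero
  ps0 <- paired_stats(c(1, 2, 3), c(1, 2, 3))
  expect_true(ps0$undefined)
  expect_true(is.na(ps0$t))
  expect_true(is.na(ps0$cohen_d_paired))
  expect_error(paired_stats(1:3, 1:4), "equal lengths")
})

test_that("tidy and glance summarise paired statistics", {
  ps <- paired_stats(c(4, 6, 9), c(3, 4, 6))
  td <- generics::tidy(ps)
  expect_equal(td$statistic, ps$t)
  expect_equal(td$cohen_d, 2)
  gl <- generics::glance(ps)
  expect_equal(gl$n, 3)
  expect_false(gl$undefined)
})
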