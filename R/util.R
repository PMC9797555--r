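# Shared low-level helpers: raster conventions, connected components,
# optimal assignment. Frames are numeric matrices [row = y, col = x];
# stacks are 3D arrays [y, x, frame]. Physical coordinates are micrometres
# with the top-left pixel centre at (0, 0).

# pixel (row, col), 1-based -> physical centre coordinates (um)
px_to_um <- function(idx_1based, pixel_size_um) (idx_1based - 1) * pixel_size_um

# physical coordinate (um) -> nearest pixel index, 1-based
um_to_px <- function(coord_um, pixel_size_um) round(coord_um / pixel_size_um) + 1

as_stack <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3) return(frames)
  if (is.matrix(frames)) return(array(frames, dim = c(dim(frames), 1)))
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    return(array(unlist(frames, use.names = FALSE), dim = c(d, length(frames))))
  }
  stop("cannot interpret input as an image stack", call. = FALSE)
}

n_frames <- function(stack) dim(as_stack(stack))[3]

# 8-connected component labelling of a logical matrix.
# Returns an integer matrix of labels (0 = background). Implemented with a
# stack-based flood fill over the foreground pixel set; EBImage's bwlabel is
# 4-connected, while skeleton/branch analysis here needs 8-connectivity.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  fg <- which(mask != 0)
  if (length(fg) == 0) return(lab)
  cur <- 0L
  # neighbour offsets in linear index space handled via (row, col) to respect borders
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% ny) + 1L
      cl <- ((p - 1L) %/% ny) + 1L
      rr <- max(1L, r - 1L):min(ny, r + 1L)
      cc <- max(1L, cl - 1L):min(nx, cl + 1L)
      for (c2 in cc) {
        base <- (c2 - 1L) * ny
        for (r2 in rr) {
          q <- base + r2
          if (mask[q] != 0 && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Optimal assignment (Hungarian algorithm with potentials, O(n^3)).
# cost: n x m matrix (rows = workers). Returns integer vector of length n,
# col assigned to each row (NA when unassigned because m < n).
# Rectangular matrices are padded to square with a cost exceeding any real one.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  k <- max(n, m)
  big <- sum(abs(cost[is.finite(cost)])) + 1
  sq <- matrix(big, k, k)
  finite_cost <- cost
  finite_cost[!is.finite(finite_cost)] <- big
  sq[seq_len(n), seq_len(m)] <- finite_cost
  # JV-style shortest augmenting paths
  u <- numeric(k + 1); v <- numeric(k + 1)
  p <- integer(k + 1)  # p[j]: row matched to column j (0 = free)
  way <- integer(k + 1)
  for (i in seq_len(k)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, k + 1)
    used <- rep(FALSE, k + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(k)) {
        if (!used[j + 1]) {
          cur <- sq[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:k) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign_row <- rep(NA_integer_, k)
  for (j in seq_len(k)) if (p[j + 1] > 0) assign_row[p[j + 1]] <- j
  out <- assign_row[seq_len(n)]
  out[out > m] <- NA_integer_
  out
}

# Separable Gaussian blur of a matrix, SD in pixels (0 = identity).
blur_matrix <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  as.matrix(EBImage::gblur(mat, sigma = sigma_px))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
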