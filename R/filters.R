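# Separable filtering primitives used by the bias estimator and the
# Laplacian-of-Gaussian stage. Filters are applied axis-by-axis as banded
# operator matrices, which keeps everything in fast dense BLAS calls even for
# full acquisition grids.

# apply an n_axis x n_axis operator matrix along one axis of a 3D array
apply_operator_axis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  x <- aperm(arr, perm)
  dp <- dim(x)
  y <- M %*% matrix(x, nrow = dp[1])
  y <- array(y, dim = dp)
  aperm(y, order(perm))
}

# row-normalized Gaussian smoothing matrix (normalized convolution: boundary
# rows renormalize over the in-grid support, avoiding edge darkening)
gaussian_operator <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  offs <- (-half):half
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  M <- matrix(0, n, n)
  for (k in seq_along(offs)) {
    j <- seq_len(n) + offs[k]
    ok <- j >= 1 & j <= n
    M[cbind(which(ok), j[ok])] <- M[cbind(which(ok), j[ok])] + w[k]
  }
  M / rowSums(M)
}

# second-difference operator with zero-gradient (Neumann) boundaries,
# scaled by 1/h^2 so responses are comparable across anisotropic axes
laplacian_operator <- function(n, h) {
  M <- matrix(0, n, n)
  diag(M) <- -2
  M[cbind(1:(n - 1), 2:n)] <- 1
  M[cbind(2:n, 1:(n - 1))] <- 1
  M[1, 1] <- -1
  M[n, n] <- -1
  M / h^2
}

# Gaussian-smooth a 3D array with a physical scale sigma_mm (per-axis sigma
# in voxels = sigma_mm / spacing); axes with sigma below ~1e-3 voxel are left
# untouched
smooth_gaussian_mm <- function(arr, voxel_size_mm, sigma_mm,
                               axes = 1:3) {
  out <- arr
  for (a in axes) {
    s <- sigma_mm / voxel_size_mm[a]
    if (s > 1e-3)
      out <- apply_operator_axis(out, gaussian_operator(dim(arr)[a], s), a)
  }
  out
}

# Laplacian-of-Gaussian response in physical units (1/mm^2 scaling)
log_response <- function(arr, voxel_size_mm, sigma_mm, per_slice = FALSE) {
  axes <- if (per_slice) 1:2 else 1:3
  sm <- smooth_gaussian_mm(arr, voxel_size_mm, sigma_mm, axes = axes)
  resp <- array(0, dim = dim(arr))
  for (a in axes)
    resp <- resp +
      apply_operator_axis(sm, laplacian_operator(dim(arr)[a],
                                                 voxel_size_mm[a]), a)
  resp
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# 6-connected components of a logical 3D mask; returns an integer array with
# 0 outside the mask and component ids 1..k inside
connected_components_3d <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  comp <- integer(n)
  idx_mask <- which(mask)
  if (length(idx_mask) == 0) return(array(comp, dim = d))
  in_mask <- logical(n)
  in_mask[idx_mask] <- TRUE
  # neighbor offsets in linear indexing, with wrap guards via coordinates
  i1 <- ((idx_mask - 1L) %% d[1]) + 1L
  rest <- (idx_mask - 1L) %/% d[1]
  i2 <- (rest %% d[2]) + 1L
  i3 <- (rest %/% d[2]) + 1L
  coord <- cbind(i1, i2, i3)
  rownames(coord) <- NULL
  pos <- integer(n)
  pos[idx_mask] <- seq_along(idx_mask)

  offs <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 1L, 0L),
               c(0L, 0L, -1L), c(0L, 0L, 1L))
  lin_off <- vapply(offs, function(o) o[1] + o[2] * d[1] +
                      o[3] * d[1] * d[2], integer(1))

  current <- 0L
  visited <- logical(length(idx_mask))
  for (start_pos in seq_along(idx_mask)) {
    if (visited[start_pos]) next
    current <- current + 1L
    frontier <- idx_mask[start_pos]
    visited[start_pos] <- TRUE
    comp[frontier] <- current
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (k in seq_along(lin_off)) {
        o <- offs[[k]]
        cand <- frontier + lin_off[k]
        fc <- coord[pos[frontier], , drop = FALSE]
        ok <- fc[, 1] + o[1] >= 1L & fc[, 1] + o[1] <= d[1] &
          fc[, 2] + o[2] >= 1L & fc[, 2] + o[2] <= d[2] &
          fc[, 3] + o[3] >= 1L & fc[, 3] + o[3] <= d[3]
        cand <- cand[ok]
        cand <- cand[in_mask[cand] & comp[cand] == 0L]
        if (length(cand) > 0) {
          comp[cand] <- current
          visited[pos[cand]] <- TRUE
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  array(comp, dim = d)
}
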