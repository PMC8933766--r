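# small, fast phantom used by most unit tests (the default-resolution spec
# is exercised where the contract is about the default geometry)
small_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(grid_shape = c(64L, 64L, 16L),
                                 cerebellum_radius_mm = 2, seed = seed),
                            list(...))
  do.call(phantom_spec, args)
}

# segment a phantom the way the pipeline does (mask = true cerebellum)
segment_phantom <- function(ph, normalize = TRUE, ...) {
  img <- if (normalize) normalize_intensity(ph$image) else ph$image
  mask <- array(ph$labels$labels %in% c(1L, 2L), dim = dim(ph$labels$labels))
  suppressWarnings(segment_wm_gm(img, mask, ...))
}

# voxelize an ellipsoid by the centre-inside rule on a given grid (test-side
# oracle for resolution-convergence checks)
voxelize_ellipsoid <- function(semi, h, n) {
  ax <- lapply(1:3, function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * h[a])
  U <- array(ax[[1]] / semi[1], n)
  V <- array(rep(ax[[2]] / semi[2], each = n[1]), n)
  W <- array(rep(ax[[3]] / semi[3], each = n[1] * n[2]), n)
  sum(U^2 + V^2 + W^2 <= 1) * prod(h)
}
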