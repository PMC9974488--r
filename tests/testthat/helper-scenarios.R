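# Small, fast scenario for imaging tests: 128 px fields, 12 cells.
small_scenario <- function(seed = 1L,
                           image = list(dim = c(128L, 128L), n_cells = 12L,
                                        radius_px = c(6, 9), background = 5,
                                        amplitude = 600, edge_px = 2),
                           ...) {
  synthetic_scenario(seed = seed, image = image, ...)
}

# Draw discs of constant value on a blank raster (hard edges, for exact
# segmentation fixtures).
draw_discs <- function(dim, centers, radius, value = 100) {
  m <- matrix(0, dim[1], dim[2])
  for (k in seq_len(nrow(centers))) {
    for (i in seq_len(dim[1])) {
      dx2 <- (i - centers[k, 1])^2
      if (dx2 > radius^2) next
      jr <- sqrt(radius^2 - dx2)
      j0 <- max(1, ceiling(centers[k, 2] - jr)); j1 <- min(dim[2], floor(centers[k, 2] + jr))
      if (j0 <= j1) m[i, j0:j1] <- value
    }
  }
  m
}
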