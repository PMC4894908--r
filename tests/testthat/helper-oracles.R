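# Independent oracles used across the suite.

# Brute-force flood-fill labeling (stack-based), first-encounter label
# order in column-major scan — the same canonical order the package uses,
# so matching labelings compare with identical().
flood_fill_label <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  dirs <- if (connectivity == 8) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  cur <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!m[i, j] || lab[i, j] != 0L) next
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in dirs) {
          ii <- p[1] + d[1]; jj <- p[2] + d[2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              m[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# labeling produced by the package, as a bare integer matrix
package_labels <- function(m) {
  p <- label_particles(binary_mask(m))
  lab <- attr(p, "labels")
  attributes(lab) <- list(dim = dim(lab))
  lab
}

# flat constant-color image helper
flat_image <- function(rgb, nr = 16, nc = 16, pixel_size = 1) {
  arr <- array(0L, dim = c(nr, nc, 3))
  for (k in 1:3) arr[, , k] <- rgb[k]
  rgb_image(arr, pixel_size = pixel_size)
}

# paint a filled disk into an rgb image (0-based center)
paint_disk_rgb <- function(img, center, radius, rgb) {
  d <- dim(img$pixels)
  rows <- seq_len(d[1]) - 1
  cols <- seq_len(d[2]) - 1
  dy <- outer(rows - center[1], rep(1, d[2]))
  dx <- outer(rep(1, d[1]), cols - center[2])
  inside <- dy^2 + dx^2 <= radius^2
  px <- img$pixels
  for (k in 1:3) {
    ch <- px[, , k]
    ch[inside] <- rgb[k]
    px[, , k] <- ch
  }
  rgb_image(px, pixel_size = img$pixel_size)
}

raster_disk <- function(radius, pad = 4) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  g <- expand.grid(i = 1:n, j = 1:n)
  m <- matrix((g$i - ctr)^2 + (g$j - ctr)^2 <= radius^2, n, n)
  m
}
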