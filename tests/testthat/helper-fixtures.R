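# Shared fixtures and independent brute-force oracles.

# Idealized scene: no noise, no shading, no background, no quantization, so
# analytic identities hold to machine precision.
clean_spec <- function(shape = c(128L, 128L), e = 0.2, seed = 1L) {
  scene_spec(shape = shape, cells = default_cells(shape, e = e),
             noise = "none", shading_amplitude = 0,
             background = c(dd = 0, da = 0, aa = 0),
             quantize = FALSE, seed = seed)
}

const_image <- function(value, nr = 32L, nc = 32L, dmax = 4095) {
  image2d(matrix(value, nr, nc), dmax)
}

make_acq <- function(dd, da, aa, dmax = 4095) {
  fret_acquisition(image2d(dd, dmax), image2d(da, dmax), image2d(aa, dmax))
}

# Independent background oracle: re-derives the documented RNG recipe (one
# seed, row origins then column origins, uniform with replacement) and
# computes every candidate mean with scalar loops; ties on the minimum go to
# the first-drawn square.
bf_background <- function(px, seed, n_squares = 30L, square_size = 15L) {
  set.seed(seed)
  h <- nrow(px); w <- ncol(px); s <- square_size
  rows <- sample.int(h - s + 1L, n_squares, replace = TRUE)
  cols <- sample.int(w - s + 1L, n_squares, replace = TRUE)
  means <- numeric(n_squares)
  for (i in seq_len(n_squares)) {
    acc <- 0
    for (r in rows[i]:(rows[i] + s - 1L))
      for (cc in cols[i]:(cols[i] + s - 1L)) acc <- acc + px[r, cc]
    means[i] <- acc / (s * s)
  }
  best <- 1L
  for (i in seq_len(n_squares)) if (means[i] < means[best]) best <- i
  list(level = means[best], origin = c(row = rows[best], col = cols[best]),
       means = means)
}

# Brute-force evaluable-pixel count for the dynamic-range masks.
bf_evaluable_count <- function(dd, aa, dmax, low = 0.10, high = 0.90) {
  n <- 0L
  for (i in seq_len(nrow(dd))) for (j in seq_len(ncol(dd))) {
    ok_dd <- dd[i, j] >= low * dmax && dd[i, j] <= high * dmax
    ok_aa <- aa[i, j] >= low * dmax && aa[i, j] <= high * dmax
    if (ok_dd && ok_aa) n <- n + 1L
  }
  n
}
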