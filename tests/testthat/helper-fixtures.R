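# Small builders shared across test files.

mk_grid <- function(values, nr = NULL, nc = NULL, ...) {
  if (!is.matrix(values)) values <- matrix(values, nr, nc)
  grid_create(values, ...)
}

# A tiny co-registered stack from a years-by-pixels matrix.
mk_stack <- function(Y, years = seq_len(nrow(Y)) + 1999L, nr = 1L) {
  nc <- ncol(Y) / nr
  annual_stack(years, lapply(seq_len(nrow(Y)), function(k) {
    grid_create(matrix(Y[k, ], nr, nc))
  }))
}

# Deterministic small scene used by several files.
tiny_scene <- function(seed = 42L, shape = c(12, 12), ...) {
  generate_scene(scene_config(shape = shape, seed = seed, ...))
}

expect_num_eq <- function(object, expected, tol = 1e-12) {
  expect_equal(object, expected, tolerance = tol)
}
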