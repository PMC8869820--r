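# Shared fixtures: a default optical configuration and analytic test masks.

test_config <- function(...) optical_config(...)

# disk mask on an n x n grid, radius r px, centred mid-grid
circle_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  xy <- expand.grid(row = seq_len(n), col = seq_len(n))
  matrix((xy$row - cy)^2 + (xy$col - cx)^2 <= r^2, n, n)
}

square_mask <- function(n, side, r0 = (n - side) %/% 2) {
  m <- matrix(FALSE, n, n)
  m[r0:(r0 + side - 1), r0:(r0 + side - 1)] <- TRUE
  m
}

ellipse_mask <- function(n, a, b, angle = 0) {
  cx <- (n + 1) / 2
  xy <- expand.grid(row = seq_len(n), col = seq_len(n))
  u <- (xy$col - cx) * cos(angle) + (xy$row - cx) * sin(angle)
  v <- -(xy$col - cx) * sin(angle) + (xy$row - cx) * cos(angle)
  matrix((u / a)^2 + (v / b)^2 <= 1, n, n)
}

# Ramanujan's ellipse perimeter approximation (exact to ~1e-9 for our
# aspect ratios); the analytic oracle for form-factor checks.
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# single fixed-parameter phantom: the lymphocyte-like reference cell
reference_phantom <- function(radius = 3.675, n_cell = 1.3497, ...) {
  phantom_population(1, radius_mean = radius, radius_sd = 0,
                     n_cell_mean = n_cell, n_cell_sd = 0, seed = 1, ...)
}
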