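test_that("a rendered phantom segments into one mask with the right area", {
  cfg <- test_config()
  img <- render_phase_image(reference_phantom(), cfg)
  seg <- segment_cells(img, 10, 400)
  expect_equal(nrow(seg), 1)
  expect_false(seg$attached[1])
  # threshold at ~0.1 rad sits just inside the projected edge, so the mask
  # area tracks pi R^2 closely
  expect_equal(seg$area_um2[1], pi * 3.675^2, tolerance = 0.03)
})

test_that("an empty phase image yields no masks", {
  cfg <- test_config()
  img <- phase_image(matrix(0, 128, 128), cfg$pixel_scale)
  expect_equal(nrow(segment_cells(img, 10, 400)), 0)
})

test_that("two overlapping phantoms are flagged attached, not split", {
  # centres 6.9 um apart: the projected disks overlap (single component)
  # but both phase apices survive as separate maxima
  cfg <- test_config(image_shape = c(192, 192))
  a <- render_phase_image(reference_phantom(center = c(6.0, 9.55)), cfg)
  b <- render_phase_image(reference_phantom(center = c(12.9, 9.55)), cfg)
  seg <- segment_cells(a$phase + b$phase, 10, 400,
                       pixel_scale = cfg$pixel_scale)
  expect_equal(nrow(seg), 1)
  expect_true(seg$attached[1])
})

test_that("masks are ordered row-major and areas gated", {
  cfg <- test_config(image_shape = c(256, 256))
  top <- render_phase_image(reference_phantom(center = c(19, 6)), cfg)
  bottom <- render_phase_image(reference_phantom(center = c(6, 19)), cfg)
  seg <- segment_cells(top$phase + bottom$phase, 10, 400,
                       pixel_scale = cfg$pixel_scale)
  expect_equal(nrow(seg), 2)
  expect_lt(seg$row_px[1], seg$row_px[2])
  # gate everything out
  expect_equal(nrow(segment_cells(top$phase, 10, 20,
                                  pixel_scale = cfg$pixel_scale)), 0)
})

test_that("form factor matches analytic shapes", {
  # exact circle from analytic area and perimeter: FF = 1 identically
  r <- 5
  ff_analytic <- 4 * pi * (pi * r^2) / (2 * pi * r)^2
  expect_equal(ff_analytic, 1)

  # rasterized estimators approach the analytic values
  circ <- compute_form_factor(circle_mask(128, 30), 1)
  expect_lt(abs(circ$form_factor - 1), 0.02)
  expect_equal(circ$area_um2, pi * 30^2, tolerance = 0.02)
  expect_equal(circ$perimeter_um, 2 * pi * 30, tolerance = 0.02)

  sq <- compute_form_factor(square_mask(128, 48), 1)
  expect_equal(sq$form_factor, pi / 4, tolerance = 0.02)

  el <- compute_form_factor(ellipse_mask(160, 60, 30), 1)
  ff_ram <- 4 * pi * (pi * 60 * 30) / ellipse_perimeter(60, 30)^2
  expect_equal(el$form_factor, ff_ram, tolerance = 0.02)

  # 45-degree square: the staircase diagonal must not inflate the perimeter
  n <- 128
  xy <- expand.grid(row = 1:n, col = 1:n)
  u <- (xy$col - 64.5 + xy$row - 64.5) / sqrt(2)
  v <- (xy$col - 64.5 - (xy$row - 64.5)) / sqrt(2)
  diam <- matrix(abs(u) <= 24 & abs(v) <= 24, n, n)
  rot <- compute_form_factor(diam, 1)
  expect_equal(rot$form_factor, pi / 4, tolerance = 0.02)

  expect_error(compute_form_factor(matrix(FALSE, 8, 8)), "empty")
})

test_that("form factor is clipped to [0, 1] with the raw value logged", {
  g <- compute_form_factor(circle_mask(96, 25), 1)
  expect_lte(g$form_factor, 1)
  expect_gte(g$form_factor, 0)
  expect_type(g$form_factor_raw, "double")
  # pixel scale cancels out of FF
  g2 <- compute_form_factor(circle_mask(96, 25), 0.1)
  expect_equal(g$form_factor, g2$form_factor)
})

test_that("volume and dry mass formulas are exact", {
  expect_equal(compute_volume(0), 0)
  expect_equal(compute_volume(3.675), (4 / 3) * pi * 3.675^3)
  expect_equal(compute_volume(3.675), 207.9, tolerance = 1e-3)
  expect_equal(compute_volume(4.533), 390.1, tolerance = 1e-3)
  expect_error(compute_volume(-1), "negative")

  expect_equal(compute_dry_mass(212, 1.337, 1.337), 0)
  expect_equal(compute_dry_mass(212, 1.3497, 1.337), (212 / 0.2) * 0.0127)
  expect_equal(compute_dry_mass(212, 1.3497, 1.337), 13.5, tolerance = 1e-2)
  # additivity in V at fixed index
  expect_equal(compute_dry_mass(100 + 150, 1.349, 1.337),
               compute_dry_mass(100, 1.349, 1.337) +
                 compute_dry_mass(150, 1.349, 1.337))
  expect_error(compute_dry_mass(10, 1.35, alpha = 0), "alpha")
  expect_error(compute_dry_mass(-5, 1.35), "negative")
})

test_that("volume agrees with numerical integration of the sphere", {
  # independent oracle: integrate the thickness profile over the disk
  r <- 3.675
  dx <- 0.002
  x <- seq(-r, r, by = dx)
  grid2 <- outer(x^2, x^2, "+")
  v_num <- sum(2 * sqrt(pmax(r^2 - grid2, 0))) * dx^2
  expect_equal(compute_volume(r), v_num, tolerance = 1e-4)
})

test_that("the sphere fit recovers noiseless phantoms almost exactly", {
  cfg <- test_config()
  ph <- reference_phantom()
  img <- render_phase_image(ph, cfg)
  seg <- segment_cells(img, 10, 400)
  fit <- fit_sphere_model(img, seg$mask[[1]], cfg)

  expect_false(fit$fit_failed)
  expect_lt(abs(fit$R_um - 3.675) / 3.675, 1e-3)
  expect_lt(abs(fit$n_cell - 1.3497) / 1.3497, 1e-3)
  expect_lt(fit$residual_rms, 1e-6)
  expect_equal(fit$V_um3, (4 / 3) * pi * fit$R_um^3)
  expect_equal(fit$DM_pg,
               (fit$V_um3 / 0.2) * (fit$n_cell - cfg$n_medium))

  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$R_um, fit$R_um)
  expect_true(glance(fit)$converged)
})

test_that("Gauss-Newton agrees with an exhaustive grid search", {
  cfg <- test_config()
  ph <- reference_phantom()
  img <- render_phase_image(ph, cfg)
  seg <- segment_cells(img, 10, 400)
  mask <- holocyte:::erode_mask(seg$mask[[1]], 2)

  idx <- which(mask, arr.ind = TRUE)
  xs <- (idx[, 2] - 1) * cfg$pixel_scale
  ys <- (idx[, 1] - 1) * cfg$pixel_scale
  obs <- img$phase[mask]
  k <- 4 * pi / cfg$wavelength
  ctr <- (cfg$image_shape - 1) / 2 * cfg$pixel_scale
  rho2 <- (xs - ctr[2])^2 + (ys - ctr[1])^2

  r_grid <- seq(3.575, 3.775, by = 0.01)
  n_grid <- seq(1.3447, 1.3547, by = 1e-4)
  sse <- matrix(NA_real_, length(r_grid), length(n_grid))
  for (i in seq_along(r_grid)) {
    s <- sqrt(pmax(r_grid[i]^2 - rho2, 0))
    for (j in seq_along(n_grid)) {
      sse[i, j] <- sum((obs - k * s * (n_grid[j] - cfg$n_medium))^2)
    }
  }
  best <- arrayInd(which.min(sse), dim(sse))
  fit <- fit_sphere_model(img, seg$mask[[1]], cfg)
  expect_lte(abs(fit$R_um - r_grid[best[1]]), 0.01 + 1e-9)
  expect_lte(abs(fit$n_cell - n_grid[best[2]]), 1e-4 + 1e-12)
})

test_that("mean volume is unbiased under phase noise", {
  cfg <- test_config()
  ph <- reference_phantom()
  img <- render_phase_image(ph, cfg)
  seg <- segment_cells(img, 10, 400)
  mask <- seg$mask[[1]]
  v_true <- ph$volume_um3

  withr::with_seed(99, {
    vols <- vapply(1:60, function(i) {
      noisy <- phase_image(img$phase + matrix(rnorm(128 * 128, 0, 0.05),
                                              128, 128),
                           cfg$pixel_scale)
      fit_sphere_model(noisy, mask, cfg)$V_um3
    }, numeric(1))
  })
  expect_lt(abs(mean(vols) - v_true) / v_true, 0.01)
})

test_that("the fit fails gracefully on degenerate inputs", {
  cfg <- test_config()
  zero <- phase_image(matrix(0, 128, 128), cfg$pixel_scale)
  mask <- circle_mask(128, 30)
  fit <- fit_sphere_model(zero, mask, cfg)
  expect_true(fit$fit_failed)
  expect_match(fit$failure_reason, "contrast")

  tiny <- matrix(FALSE, 128, 128)
  tiny[60:62, 60:62] <- TRUE
  img <- render_phase_image(reference_phantom(), cfg)
  expect_true(fit_sphere_model(img, tiny, cfg)$fit_failed)
})

test_that("recovered parameters are pixel-scale equivariant", {
  ph <- reference_phantom()
  fit_at <- function(px, shape) {
    cfg <- optical_config(pixel_scale = px, image_shape = shape)
    img <- render_phase_image(ph, cfg)
    seg <- segment_cells(img, 10, 400)
    fit_sphere_model(img, seg$mask[[1]], cfg)
  }
  f1 <- fit_at(0.1, c(128, 128))
  f2 <- fit_at(0.05, c(192, 192))
  expect_lt(abs(f2$R_um / f1$R_um - 1), 0.002)
  expect_lt(abs(f2$n_cell / f1$n_cell - 1), 0.002)
})

test_that("QC rules partition measurements with reasons", {
  cfg <- test_config()
  img <- render_phase_image(reference_phantom(), cfg)
  cells <- measure_cells(img, cfg)
  res <- qc_filter(cells, qc_rules())
  expect_equal(nrow(res$kept), 1)
  expect_equal(nrow(res$excluded), 0)

  # a 3:1 elongated spheroid has FF ~ 0.66 and is excluded as deformed
  sp <- phantom_population(1, 2.3, 0, seed = 1, shape = "spheroid",
                           axis_ratio = 3)
  img_sp <- render_phase_image(sp, cfg)
  cells_sp <- measure_cells(img_sp, cfg)
  expect_lt(cells_sp$FF[1], 0.7)
  res_sp <- qc_filter(cells_sp, qc_rules(ff_min = 0.7))
  expect_equal(nrow(res_sp$excluded), 1)
  expect_equal(res_sp$excluded$qc_reason, "deformed")

  # thresholds at extremes: identity filter
  lax <- qc_rules(ff_min = 0, residual_max = Inf,
                  volume_gates = list())
  res_all <- qc_filter(dplyr::bind_rows(cells, cells_sp), lax)
  expect_equal(nrow(res_all$kept), 2)
  expect_equal(nrow(res_all$excluded), 0)

  # kept + excluded partitions the input
  strict <- qc_rules(volume_gates = list(lymphocyte = c(300, 400)))
  res_gate <- qc_filter(cells, strict)
  expect_equal(nrow(res_gate$kept) + nrow(res_gate$excluded), nrow(cells))
  expect_equal(res_gate$excluded$qc_reason, "volume_gate")
})
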