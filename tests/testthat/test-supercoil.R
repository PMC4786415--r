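test_that("local axis recovers the twist of an ideal straight helix", {
  p <- crick_params(n_chains = 1, superhelix_radius = 0,
                    twist_per_residue = 100)
  coil <- generate_crick_coil(p, 24)
  ax <- local_helix_axis(coil$chains[[1]]$CA)
  expect_equal(mean(ax$twist, na.rm = TRUE), 100, tolerance = 0.1)
  # rigid-transform invariance of the twist
  tr <- random_rigid_transform(seed = 9)
  ca2 <- transform_coords(coil$chains[[1]]$CA, tr$R, tr$shift)
  ax2 <- local_helix_axis(ca2)
  expect_equal(ax2$twist, ax$twist, tolerance = 1e-6)
})

test_that("short and degenerate traces are invalid rather than errors", {
  expect_true(all(!local_helix_axis(matrix(rnorm(9), 3, 3))$valid))
  line <- cbind(seq_len(8) * 1.5, 0, 0) # straight-line trace
  expect_true(all(!local_helix_axis(line)$valid))
})

test_that("the bundle axis of a C3 bundle is the symmetry axis", {
  coil <- generate_crick_coil(crick_params(n_chains = 3), 28)
  ax <- bundle_axis(coil$chains)
  ok <- !is.na(ax$points[, 1])
  radial <- sqrt(rowSums(ax$points[ok, 1:2, drop = FALSE]^2))
  expect_lt(max(radial), 0.05)
  expect_gt(abs(ax$dir[3]), 0.9999)
  expect_error(bundle_axis(coil$chains[1]), "at least 2")
  # equivariance: translating the bundle translates the axis
  shifted <- lapply(coil$chains, betalayer:::transform_chain,
                    R = diag(3), shift = c(5, -3, 2))
  ax2 <- bundle_axis(shifted)
  expect_equal(ax2$points[ok, ], ax$points[ok, ] +
                 matrix(c(5, -3, 2), sum(ok), 3, byrow = TRUE),
               tolerance = 1e-8)
})

test_that("generated coils measure their nominal periodicity", {
  # straight helix at the unperturbed-helix twist
  p <- crick_params(n_chains = 1, superhelix_radius = 0,
                    twist_per_residue = 360 / 3.63)
  m <- generate_crick_coil(p, 28)
  tr <- periodicity_trace(m$chains[[1]], bundle_axis_line(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(mean(tr$periodicity, na.rm = TRUE), 3.63, tolerance = 0.02)
  # supercoiled trimers across the accessible band
  for (P in c(3.33, 3.5, 3.6, 3.67, 3.75, 3.8)) {
    coil <- generate_crick_coil(
      crick_params(n_chains = 3, supercoil_periodicity = P), 28)
    trace <- periodicity_trace(coil$chains[[1]], bundle_axis(coil$chains))
    expect_equal(mean(trace$periodicity, na.rm = TRUE), P, tolerance = 0.03,
                 label = sprintf("P=%.2f", P))
  }
})

test_that("trimer chains are exact 120-degree copies", {
  coil <- generate_crick_coil(crick_params(n_chains = 3), 20)
  R <- betalayer:::rotation_matrix(c(0, 0, 1), 120)
  rotated <- transform_coords(coil$chains[["A"]]$CA, R)
  expect_equal(rotated, coil$chains[["B"]]$CA, tolerance = 1e-9)
})

test_that("smoothing is a centered shrinking-window moving average", {
  expect_equal(smooth_trace(rep(3.5, 6), 3), rep(3.5, 6))
  spike <- c(3.5, 3.5, 4.1, 3.5, 3.5)
  expect_equal(smooth_trace(spike, 3)[3], (3.5 + 4.1 + 3.5) / 3)
  expect_equal(smooth_trace(spike, 1), spike)
  expect_error(smooth_trace(spike, 2), "odd")
  # length preserved, NA stays NA
  x <- c(NA, 1, 2, 3, NA)
  s <- smooth_trace(x, 3)
  expect_length(s, 5)
  expect_true(is.na(s[1]) && is.na(s[5]))
})

test_that("heptad coils get cyclically advancing register labels", {
  coil <- generate_crick_coil(
    crick_params(n_chains = 3, supercoil_periodicity = 3.5, phase = 25.714), 28)
  trace <- periodicity_trace(coil$chains[[1]], bundle_axis(coil$chains))
  reg <- assign_register(trace)
  lab <- reg[!is.na(reg)]
  idx <- match(lab, letters[1:7])
  expect_true(all(diff(idx) %% 7 == 1))
  # phase closure: consecutive a positions are one heptad (2 turns) apart
  a_pos <- which(reg == "a")
  expect_true(all(diff(a_pos) == 7))
  crick_a <- trace$crick[a_pos]
  expect_true(all(abs(wrap_angle(diff(crick_a))) < 2))
})

test_that("register labels survive rigid transforms and renaming", {
  model <- base_fixture("nonad")
  layers <- detect_beta_layers(model)
  axis <- bundle_axis_line(c(0, 0, 0), c(0, 0, 1))
  ref <- assign_register(periodicity_trace(model$chains[[1]], axis), layers)
  tr <- random_rigid_transform(seed = 33)
  m2 <- betalayer:::transform_model(model, tr$R, tr$shift)
  axis2 <- bundle_axis_line(as.numeric(tr$R %*% c(0, 0, 0)) + tr$shift,
                            as.numeric(tr$R %*% c(0, 0, 1)))
  l2 <- detect_beta_layers(m2)
  got <- assign_register(periodicity_trace(m2$chains[[1]], axis2), l2)
  expect_equal(got, ref)
})
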