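test_that("dihedral reproduces planar references and the sign convention", {
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)), 180)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  # sign fixed by the IUPAC convention, frozen from the independent
  # vector implementation in bio3d::torsion.xyz
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)), -90)
})

test_that("dihedral agrees with an independent implementation on random input", {
  set.seed(101)
  for (k in 1:25) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    mine <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(p)))
    expect_equal(mine, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("dihedral is rigid-transform invariant and mirror-antisymmetric", {
  set.seed(7)
  p <- matrix(rnorm(12, sd = 3), 4, 3)
  d0 <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
  for (k in 1:5) {
    tr <- random_rigid_transform(seed = k)
    q <- transform_coords(p, tr$R, tr$shift)
    expect_equal(dihedral(q[1, ], q[2, ], q[3, ], q[4, ]), d0,
                 tolerance = 1e-9)
  }
  m <- p
  m[, 3] <- -m[, 3] # mirror
  expect_equal(dihedral(m[1, ], m[2, ], m[3, ], m[4, ]), -d0,
               tolerance = 1e-9)
})

test_that("degenerate geometry yields NA, not an error", {
  expect_true(is.na(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))))
  expect_true(is.na(dihedral(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0))))
})

test_that("torsion-built backbones reproduce their inputs exactly", {
  set.seed(11)
  phi <- runif(15, -180, 179)
  psi <- runif(15, -180, 179)
  ch <- build_backbone_from_torsions(phi, psi)
  tt <- compute_torsions(ch)
  expect_equal(tt$phi[-1], phi[-1], tolerance = 1e-9)
  expect_equal(tt$psi[-15], psi[-15], tolerance = 1e-9)
  expect_true(is.na(tt$phi[1]))
  expect_true(is.na(tt$psi[15]))
})

test_that("an ideal alpha-helix has the canonical rise", {
  h <- build_backbone_from_torsions(rep(-57.8, 20), rep(-47, 20))
  centered <- scale(h$CA, scale = FALSE)
  ax <- svd(centered)$v[, 1]
  rise <- abs(mean(diff(h$CA %*% ax)))
  expect_equal(rise, 1.5, tolerance = 0.1)
})

test_that("a single residue builds without torsions and without error", {
  ch <- build_backbone_from_torsions(NA_real_, NA_real_)
  expect_equal(nrow(ch$res), 1L)
  tt <- compute_torsions(ch)
  expect_true(all(is.na(c(tt$phi, tt$psi))))
})
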