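test_that("Ramachandran boxes classify with inclusive boundaries", {
  expect_equal(classify_ss(-65, -40), "alpha")
  expect_equal(classify_ss(-120, 130), "beta")
  expect_equal(classify_ss(-30, -40), "other") # phi outside -180..-40
  # boundaries inclusive
  expect_equal(classify_ss(-40, -10), "alpha")
  expect_equal(classify_ss(-40, 20), "beta")
  expect_equal(classify_ss(-180, 180), "beta")
  expect_equal(classify_ss(-39.99, -40), "other")
  expect_equal(classify_ss(NA, -40), "undefined")
})

test_that("no torsion pair is both alpha and beta (boxes disjoint in psi)", {
  set.seed(3)
  phi <- runif(500, -180, 180)
  psi <- runif(500, -180, 180)
  cls <- classify_ss(phi, psi)
  # scan the boundary grid too
  grid <- expand.grid(phi = c(-180, -40, -40.0001), psi = c(-70, -10, 20, 180))
  cls2 <- classify_ss(grid$phi, grid$psi)
  expect_true(all(cls %in% c("alpha", "beta", "other")))
  expect_true(all(cls2 %in% c("alpha", "beta", "other")))
})

test_that("torsions are invariant under rigid transforms of the model", {
  set.seed(5)
  ch <- build_backbone_from_torsions(runif(10, -170, 170), runif(10, -170, 170))
  t0 <- compute_torsions(ch)
  for (k in 1:5) {
    tr <- random_rigid_transform(seed = 40 + k)
    ch2 <- betalayer:::transform_chain(ch, tr$R, tr$shift)
    t1 <- compute_torsions(ch2)
    expect_equal(t1$phi, t0$phi, tolerance = 1e-6)
    expect_equal(t1$psi, t0$psi, tolerance = 1e-6)
  }
})

test_that("incomplete residues interrupt torsion computation", {
  ch <- build_backbone_from_torsions(rep(-57.8, 8), rep(-47, 8))
  ch$O[4, ] <- NA # lose an atom of residue 4
  ch2 <- backbone_chain(ch$chain_id, ch$res$resno, ch$res$aa,
                        ch$N, ch$CA, ch$C, ch$O)
  tt <- compute_torsions(ch2)
  expect_true(all(is.na(c(tt$phi[4], tt$psi[4]))))
  expect_equal(tt$ss[4], "undefined")
  # neighbors lose the torsion crossing the incomplete residue
  expect_true(is.na(tt$psi[3]))
  expect_true(is.na(tt$phi[5]))
})

test_that("backbone hydrogen bonds use an inclusive distance cutoff", {
  place <- function(n_xyz, o_xyz) {
    backbone_chain("X", 1L, "A",
                   N = matrix(n_xyz, 1), CA = matrix(n_xyz + c(1.4, 0, 0), 1),
                   C = matrix(n_xyz + c(2, 1, 0), 1),
                   O = matrix(o_xyz, 1))
  }
  a <- place(c(0, 0, 0), c(50, 0, 0))
  b <- place(c(2.9, 0, 0), c(60, 0, 0)) # N(b) 2.9 A from ... nothing; O far
  # one direction in range: N(a)=origin, O(b)=60 -> far; N(b)-O(a) far too
  b29 <- place(c(100, 0, 0), c(2.9, 0, 0)) # O at 2.9 from N(a)
  hb <- backbone_hbonds(a, 1, b29, 1)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$n_o_distance, 2.9)
  # exactly at the cutoff counts
  b35 <- place(c(100, 0, 0), c(3.5, 0, 0))
  expect_equal(nrow(backbone_hbonds(a, 1, b35, 1)), 1L)
  b351 <- place(c(100, 0, 0), c(3.5001, 0, 0))
  expect_equal(nrow(backbone_hbonds(a, 1, b351, 1)), 0L)
  # both directions within range give two contacts:
  # N(a)=0 with O(b) at 3.0, and O(a)=50 with N(b) at 47.2
  a2 <- place(c(0, 0, 0), c(50, 0, 0))
  both <- place(c(47.2, 0, 0), c(3.0, 0, 0))
  expect_equal(nrow(backbone_hbonds(a2, 1, both, 1)), 2L)
  # missing atoms warn and return empty
  am <- a; am$N[1, ] <- NA
  expect_warning(hb0 <- backbone_hbonds(am, 1, b29, 1), "missing")
  expect_equal(nrow(hb0), 0L)
})
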