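test_that("window scan matches exhaustive enumeration on toy class runs", {
  # brute-force oracle: test every 7-residue window against both patterns
  oracle <- function(classes) {
    pats <- list(c("beta", "beta", "beta", "alpha", "alpha", "alpha", "alpha"),
                 c("alpha", "alpha", "alpha", "alpha", "beta", "beta", "beta"))
    found <- integer(0)
    for (s in seq_len(max(0, length(classes) - 6))) {
      w <- classes[s:(s + 6)]
      if (all(w == pats[[1]])) found <- c(found, s)
      if (all(w == pats[[2]])) found <- c(found, s + 4)
    }
    sort(unique(found))
  }
  runs <- list(
    c("alpha", "alpha", "alpha", "alpha", "beta", "beta", "beta",
      "alpha", "alpha", "alpha", "alpha"),
    c("alpha", "alpha", "alpha", "beta", "beta", "beta",
      "alpha", "alpha", "alpha", "alpha"),
    rep("alpha", 12),
    rep("beta", 12),
    c(rep("alpha", 4), rep("beta", 3), rep("other", 1), rep("alpha", 4)))
  for (run in runs) {
    got <- scan_windows(class_run_series(run))
    expect_equal(got$beta1_idx, oracle(run))
  }
  # the symmetric run matches via both patterns, merged to one candidate
  both <- scan_windows(class_run_series(runs[[1]]))
  expect_equal(nrow(both), 1L)
  expect_equal(both$patterns, "aaaabbb,bbbaaaa")
  expect_equal(both$beta2_resno, 6L)
  # only 3 upstream alphas: found by bbbaaaa alone
  one <- scan_windows(class_run_series(runs[[2]]))
  expect_equal(one$patterns, "bbbaaaa")
})

test_that("windows are not matched across segment breaks", {
  ts <- class_run_series(c(rep("alpha", 4), rep("beta", 3), rep("alpha", 4)))
  ts$segment[6:11] <- 2L # break inside the strand
  expect_equal(nrow(scan_windows(ts)), 0L)
})

test_that("planted fixtures are detected with exact central residues", {
  for (sp in c("nonad", "hexad", "tandem-hexad")) {
    model <- base_fixture(sp)
    expect_true(battery_exact(model), label = sp)
    layers <- detect_beta_layers(model)
    for (ly in layers) {
      expect_equal(ly$n_strands, 3L)
      expect_true(ly$canonical)
    }
  }
})

test_that("isolated strands and alpha-only bundles yield no layers", {
  coil <- generate_crick_coil(crick_params(n_chains = 3), 28)
  expect_length(detect_beta_layers(coil), 0L)
  # a single chain of a fixture: candidate present but no partner
  model <- base_fixture("nonad")
  lone <- structure_model("lone", model$chains[1])
  tors <- compute_torsions(lone$chains[[1]])
  expect_gte(nrow(scan_windows(tors)), 1L)
  expect_length(detect_beta_layers(lone), 0L)
})

test_that("strands within one chain can pair (pseudo-threefold monomer)", {
  # concatenate the three fixture chains into one chain with renumbered
  # residues and large sequence gaps: same geometry, single chain id
  model <- base_fixture("nonad")
  chs <- model$chains
  off <- c(0L, 100L, 200L)
  resno <- c(); aa <- c(); N <- NULL; CA <- NULL; C <- NULL; O <- NULL
  for (k in 1:3) {
    ch <- chs[[k]]
    resno <- c(resno, ch$res$resno + off[k])
    aa <- c(aa, ch$res$aa)
    N <- rbind(N, ch$N); CA <- rbind(CA, ch$CA)
    C <- rbind(C, ch$C); O <- rbind(O, ch$O)
  }
  mono <- structure_model("mono",
                          list(backbone_chain("A", resno, aa, N, CA, C, O)))
  layers <- detect_beta_layers(mono)
  expect_length(layers, 1L)
  expect_equal(layers[[1]]$n_strands, 3L)
  expect_equal(sort(layers[[1]]$strands$beta2_resno), c(16L, 116L, 216L))
})

test_that("detection is invariant under rigid transforms and chain relabeling", {
  model <- base_fixture("nonad")
  ref <- layer_report(detect_beta_layers(model))
  for (k in 1:3) {
    tr <- random_rigid_transform(seed = 70 + k)
    m2 <- betalayer:::transform_model(model, tr$R, tr$shift)
    got <- layer_report(detect_beta_layers(m2))
    expect_equal(got, ref)
  }
  relab <- model
  names(relab$chains) <- NULL
  relab$chains <- rev(relab$chains)
  for (i in seq_along(relab$chains)) {
    relab$chains[[i]]$chain_id <- c("X", "Y", "Z")[i]
  }
  relab <- structure_model("relab", relab$chains)
  got <- detect_beta_layers(relab)
  expect_length(got, 1L)
  expect_equal(sort(got[[1]]$strands$chain), c("X", "Y", "Z"))
  expect_equal(got[[1]]$strands$beta2_resno, rep(16L, 3))
})

test_that("raising the hydrogen-bond cutoff never loses layers", {
  model <- base_fixture("hexad")
  counts <- vapply(c(2.8, 3.2, 3.5, 4.0, 4.5),
                   function(cut) length(detect_beta_layers(model, cutoff = cut)),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("inflating the bundle radius beyond the criterion removes all layers", {
  ann <- attr(base_fixture("nonad"), "annotation")
  inflated <- generate_beta_layer_fixture(
    "nonad", bundle_radius = ann$bundle_radius + 3)
  expect_length(detect_beta_layers(inflated), 0L)
})

test_that("capping follows the beta1 residue and transitions the flanks", {
  # KAD -> C-cap, MAT -> N-cap, VYT -> N-cap
  model <- base_fixture("tandem-hexad")
  layers <- detect_beta_layers(model)
  expect_equal(vapply(layers, function(l) l$strands$sequence[1], character(1)),
               c("KAD", "VYT"))
  expect_equal(vapply(layers, function(l) l$capping, character(1)),
               c("C-cap", "N-cap"))
  mat <- detect_beta_layers(base_fixture("nonad"))[[1]]
  expect_equal(mat$strands$sequence[1], "MAT")
  expect_equal(mat$capping, "N-cap")
  # helical flanks on both sides: an internal coiled-coil layer
  expect_equal(mat$transition, "cc-to-cc")
})

test_that("transition labels follow the flanking classes", {
  mk_layer <- function(classes, b1_idx) {
    ts <- class_run_series(classes)
    structure(list(strands = data.frame(
      chain = "A", beta1_resno = b1_idx, beta2_resno = b1_idx + 1,
      beta3_resno = b1_idx + 2, beta1_idx = b1_idx,
      sequence = "MAT", patterns = "bbbaaaa", stringsAsFactors = FALSE),
      n_strands = 3L, canonical = TRUE, hbonds = NULL,
      capping = NA, transition = NA), class = "beta_layer")
  }
  near_start <- c("alpha", "alpha", "beta", "beta", "beta",
                  rep("alpha", 6))
  ly <- annotate_transition(mk_layer(near_start, 3L),
                            class_run_series(near_start))
  expect_equal(ly$transition, "Nterm-to-cc")
  into_beta <- c(rep("alpha", 5), "beta", "beta", "beta",
                 "beta", "beta", "other", "other")
  ly <- annotate_transition(mk_layer(into_beta, 6L),
                            class_run_series(into_beta))
  expect_equal(ly$transition, "cc-to-beta")
  from_beta <- c("other", "beta", "beta", "beta", "beta", "beta",
                 rep("alpha", 5))
  ly <- annotate_transition(mk_layer(from_beta, 4L),
                            class_run_series(from_beta))
  expect_equal(ly$transition, "beta-to-cc")
})

test_that("small coordinate noise leaves the battery detection intact", {
  base <- base_fixture("nonad")
  for (sd in 1:10) {
    noisy <- perturb(base, 0.02, seed = sd)
    expect_true(battery_exact(noisy), label = paste("seed", sd))
  }
  # determinism: the same seed reproduces coordinates exactly
  a <- perturb(base, 0.1, seed = 5)
  b <- perturb(base, 0.1, seed = 5)
  expect_identical(a$chains[["A"]]$CA, b$chains[["A"]]$CA)
  expect_identical(perturb(base, 0, seed = 1)$chains[["A"]]$CA,
                   base$chains[["A"]]$CA)
})
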