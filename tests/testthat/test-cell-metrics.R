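test_that("strain energy matches the closed-form value for uniform fields", {
  # T = 100 Pa parallel to u = 0.01 um over a total area of 100 um^2
  sub <- SubstrateModel(12000, 0.5, pixelSize = 0.16)
  spacing <- 1 / 0.16            # node area = 1 um^2
  tr <- TractionGrid(matrix(100, 10, 10), matrix(0, 10, 10),
                     spacing = spacing)
  u <- DisplacementGrid(matrix(0.01, 10, 10), matrix(0, 10, 10),
                        spacing = spacing, unit = "um")
  expect_equal(strainEnergy(tr, u, sub), 5e-17, tolerance = 1e-12)

  zero <- TractionGrid(matrix(0, 10, 10), matrix(0, 10, 10),
                       spacing = spacing)
  expect_equal(strainEnergy(zero, u, sub), 0)

  # orthogonal T and u store no energy
  uo <- DisplacementGrid(matrix(0, 10, 10), matrix(0.01, 10, 10),
                         spacing = spacing, unit = "um")
  expect_equal(strainEnergy(tr, uo, sub), 0)

  # px-tagged displacement is converted internally
  upx <- DisplacementGrid(matrix(0.01 / 0.16, 10, 10), matrix(0, 10, 10),
                          spacing = spacing, unit = "px")
  expect_equal(strainEnergy(tr, upx, sub), 5e-17, tolerance = 1e-12)

  mismatched <- DisplacementGrid(matrix(0, 5, 5), matrix(0, 5, 5),
                                 spacing = spacing, unit = "um")
  expect_error(strainEnergy(tr, mismatched, sub), "same grid")
})

test_that("strain energy scales quadratically with the field amplitude", {
  sub <- testSubstrate()
  set.seed(13)
  tx <- matrix(rnorm(64, 0, 50), 8); ty <- matrix(rnorm(64, 0, 50), 8)
  ux <- matrix(rnorm(64, 0, 0.1), 8); uy <- matrix(rnorm(64, 0, 0.1), 8)
  tr1 <- TractionGrid(tx, ty, spacing = 8)
  u1 <- DisplacementGrid(ux, uy, spacing = 8, unit = "um")
  tr3 <- TractionGrid(3 * tx, 3 * ty, spacing = 8)
  u3 <- DisplacementGrid(3 * ux, 3 * uy, spacing = 8, unit = "um")
  expect_equal(strainEnergy(tr3, u3, sub), 9 * strainEnergy(tr1, u1, sub))
})

test_that("region statistics agree with a brute-force scan", {
  # single nonzero node with components (3, 4): max = mean = 5
  tx <- matrix(0, 8, 8); ty <- matrix(0, 8, 8)
  tx[4, 5] <- 3; ty[4, 5] <- 4
  tr <- TractionGrid(tx, ty, spacing = 1)
  mask <- matrix(TRUE, 8, 8)
  s <- tractionInRegion(tr, mask)
  expect_equal(unname(s["max"]), 5)
  # mean over all 64 nodes includes the zeros
  expect_equal(unname(s["mean"]), 5 / 64)
  maskOne <- matrix(FALSE, 8, 8); maskOne[4, 5] <- TRUE
  sOne <- tractionInRegion(tr, maskOne)
  expect_equal(unname(sOne["max"]), 5)
  expect_equal(unname(sOne["mean"]), 5)

  # random field on a 16 x 16 grid vs exhaustive scan inside the mask
  set.seed(23)
  tr2 <- TractionGrid(matrix(rnorm(256, 0, 100), 16),
                      matrix(rnorm(256, 0, 100), 16), spacing = 1)
  mask2 <- matrix(runif(256) > 0.5, 16, 16)
  s2 <- tractionInRegion(tr2, mask2)
  m <- magnitude(tr2)
  ref <- m[mask2]  # spacing 1, origin (1,1): node [i,j] is pixel (j,i)
  expect_equal(unname(s2["max"]), max(ref))
  expect_equal(unname(s2["mean"]), mean(ref))

  # hotspot excluded from the mask must not leak into the maximum
  hot <- which(m == max(m), arr.ind = TRUE)
  mask3 <- matrix(TRUE, 16, 16); mask3[hot] <- FALSE
  expect_equal(unname(tractionInRegion(tr2, mask3)["max"]), max(m[mask3]))

  zero <- TractionGrid(matrix(0, 8, 8), matrix(0, 8, 8), spacing = 1)
  expect_equal(unname(tractionInRegion(zero, mask)), c(0, 0))
  expect_error(tractionInRegion(tr, matrix(FALSE, 8, 8)), "empty")
})

test_that("mean traction never exceeds max traction", {
  set.seed(29)
  for (i in 1:5) {
    tr <- TractionGrid(matrix(rnorm(100, 0, 80), 10),
                       matrix(rnorm(100, 0, 80), 10), spacing = 1)
    mask <- matrix(runif(100) > 0.3, 10, 10)
    s <- tractionInRegion(tr, mask)
    expect_lte(s["mean"], s["max"])
  }
})

test_that("measureCells tabulates regions and isolates per-cell failures", {
  sub <- testSubstrate()
  tx <- matrix(0, 16, 16); ty <- matrix(0, 16, 16)
  tx[4, 4] <- 60; tx[12, 12] <- 90
  tr <- TractionGrid(tx, ty, spacing = 1)
  u <- DisplacementGrid(matrix(0.01, 16, 16), matrix(0, 16, 16),
                        spacing = 1, unit = "um")
  mA <- matrix(FALSE, 16, 16); mA[1:8, 1:8] <- TRUE
  mB <- matrix(FALSE, 16, 16); mB[9:16, 9:16] <- TRUE
  regions <- list(list(mask = mA, cellId = "a", group = "g1"),
                  list(mask = mB, cellId = "b", group = "g2"))
  out <- measureCells(tr, u, regions, sub)
  expect_equal(nrow(out), 2)
  expect_equal(out$max_traction_pa, c(60, 90))
  expect_equal(out$group, c("g1", "g2"))
  # strain energy is a full-field-of-view quantity: identical per cell
  expect_equal(out$strain_energy_j[1], out$strain_energy_j[2])

  expect_equal(nrow(measureCells(tr, u, list(), sub)), 0)

  badRegions <- c(regions,
                  list(list(mask = matrix(FALSE, 16, 16), cellId = "c",
                            group = "g1")))
  expect_warning(out2 <- measureCells(tr, u, badRegions, sub),
                 "'c' skipped")
  expect_equal(nrow(out2), 2)
})
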