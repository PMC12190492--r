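test_that("Green's tensor matches closed-form values and symmetries", {
  s <- SubstrateModel(youngModulus = 1, poissonRatio = 0.5, pixelSize = 1)
  expect_equal(greensTensorFourier(1, 0, s),
               matrix(c(1.5, 0, 0, 3.0), 2, 2), tolerance = 1e-12)
  expect_equal(greensTensorFourier(0, 1, s),
               matrix(c(3.0, 0, 0, 1.5), 2, 2), tolerance = 1e-12)
  expect_equal(greensTensorFourier(1, 1, s),
               (3 / 2^1.5) * matrix(c(1.5, -0.5, -0.5, 1.5), 2, 2),
               tolerance = 1e-12)
  # scales as 1/E
  s2 <- SubstrateModel(youngModulus = 12000, poissonRatio = 0.5)
  expect_equal(greensTensorFourier(1, 0, s2),
               greensTensorFourier(1, 0, s) / 12000)
  # symmetric positive definite away from k = 0
  for (k in list(c(0.3, -1.2), c(2, 0.01), c(-1, -1))) {
    G <- greensTensorFourier(k[1], k[2], s2)
    expect_equal(G[1, 2], G[2, 1])
    expect_true(all(eigen(G, symmetric = TRUE)$values > 0))
  }
  expect_error(greensTensorFourier(0, 0, s), "zero wavevector")
})

test_that("forward solver is linear and handles the zero field", {
  sub <- testSubstrate()
  zero <- TractionGrid(matrix(0, 16, 16), matrix(0, 16, 16))
  u0 <- forwardDisplacement(zero, sub)
  expect_equal(max(abs(vectorX(u0))), 0)
  expect_equal(max(abs(vectorY(u0))), 0)
  expect_identical(fieldUnit(u0), "um")

  tr <- makeTractionPattern("circular_patch", 400, radius = 4,
                            imageDim = c(32, 32), spacing = 1)
  u1 <- forwardDisplacement(tr, sub)
  tr3 <- TractionGrid(3 * vectorX(tr), 3 * vectorY(tr),
                      spacing = gridSpacing(tr))
  u3 <- forwardDisplacement(tr3, sub)
  expect_equal(vectorX(u3), 3 * vectorX(u1), tolerance = 1e-12)
  expect_equal(vectorY(u3), 3 * vectorY(u1), tolerance = 1e-12)

  bad <- TractionGrid(matrix(NaN, 8, 8), matrix(0, 8, 8))
  expect_error(forwardDisplacement(bad, sub), "non-finite")
})

test_that("forward solver is translation-equivariant on the periodic grid", {
  sub <- testSubstrate()
  tr <- makeTractionPattern("inward_dipole", 300, radius = 4,
                            imageDim = c(32, 32), spacing = 1,
                            separation = 12)
  u <- forwardDisplacement(tr, sub)
  roll <- function(m, dy, dx) {
    nr <- nrow(m); nc <- ncol(m)
    m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
  }
  trS <- TractionGrid(roll(vectorX(tr), 5, -3), roll(vectorY(tr), 5, -3),
                      spacing = 1)
  uS <- forwardDisplacement(trS, sub)
  expect_equal(vectorX(uS), roll(vectorX(u), 5, -3), tolerance = 1e-10)
  expect_equal(vectorY(uS), roll(vectorY(u), 5, -3), tolerance = 1e-10)
})

test_that("FFT forward solution matches the direct Boussinesq convolution", {
  sub <- testSubstrate()
  tr <- makeTractionPattern("circular_patch", 1000, radius = 10,
                            imageDim = c(64, 64), spacing = 1)
  uF <- forwardDisplacement(tr, sub, pad = TRUE)
  uD <- forwardDisplacementDirect(tr, sub)
  ctr <- 17:48  # central 32 x 32
  dm <- function(m) m[ctr, ctr] - mean(m[ctr, ctr])
  num <- sqrt(mean((dm(vectorX(uF)) - dm(vectorX(uD)))^2 +
                   (dm(vectorY(uF)) - dm(vectorY(uD)))^2))
  den <- sqrt(mean(dm(vectorX(uD))^2 + dm(vectorY(uD))^2))
  expect_lt(num / den, 0.02)
})

test_that("forward/inverse round trip at lambda = 0 is exact", {
  sub <- testSubstrate()
  tr <- makeTractionPattern("inward_dipole", 500, radius = 6,
                            imageDim = c(64, 64), spacing = 1,
                            separation = 24)
  u <- forwardDisplacement(tr, sub, pad = FALSE)
  rec <- reconstructTraction(u, sub, lambda = 0, pad = FALSE)
  relErr <- sqrt(mean((vectorX(rec) - vectorX(tr))^2 +
                      (vectorY(rec) - vectorY(tr))^2)) /
            sqrt(mean(vectorX(tr)^2 + vectorY(tr)^2))
  expect_lt(relErr, 1e-8)
})

test_that("traction norm is non-increasing in the regularization strength", {
  sub <- testSubstrate()
  tr <- makeTractionPattern("inward_dipole", 500, radius = 6,
                            imageDim = c(64, 64), spacing = 1,
                            separation = 24)
  u <- forwardDisplacement(tr, sub)
  set.seed(3)
  un <- DisplacementGrid(vectorX(u) + rnorm(64^2, 0, 0.01),
                         vectorY(u) + rnorm(64^2, 0, 0.01),
                         spacing = 1, unit = "um")
  norms <- vapply(c(0, 1e-6, 2.47e-5, 1e-3), function(l) {
    rec <- reconstructTraction(un, sub, lambda = l)
    sqrt(sum(vectorX(rec)^2 + vectorY(rec)^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-9 * norms[1]))
})

test_that("reconstructed traction has zero spatial mean", {
  sub <- testSubstrate()
  set.seed(8)
  un <- DisplacementGrid(matrix(rnorm(32^2, 0.3, 0.05), 32),
                         matrix(rnorm(32^2, -0.1, 0.05), 32),
                         spacing = 1, unit = "px")
  rec <- reconstructTraction(un, sub, pad = FALSE)
  expect_lt(abs(mean(vectorX(rec))), 1e-8 * max(abs(vectorX(rec))))
  expect_lt(abs(mean(vectorY(rec))), 1e-8 * max(abs(vectorY(rec))))
  # with taper-and-pad the balance holds over the padded domain, so the
  # cropped field's mean is only approximately zero
  recP <- reconstructTraction(un, sub, pad = TRUE)
  expect_lt(abs(mean(vectorX(recP))), 0.01 * max(abs(vectorX(recP))))
})

test_that("noisy displacement still recovers the patch traction scale", {
  # 64 x 64 nodes at the 8 px analysis spacing, radius 10 nodes,
  # node-wise noise 0.05 px, pre-inversion smoothing as in the pipeline
  sub <- testSubstrate()
  tr <- makeTractionPattern("circular_patch", 1000, radius = 80,
                            imageDim = c(512, 512), spacing = 8)
  u <- forwardDisplacement(tr, sub, pad = TRUE)
  set.seed(42)
  ux <- matrix(vectorX(u) / pixelSize(sub) + rnorm(64^2, 0, 0.05), 64)
  uy <- matrix(vectorY(u) / pixelSize(sub) + rnorm(64^2, 0, 0.05), 64)
  sx <- EBImage::gblur(ux, 0.75, boundary = "replicate")
  sy <- EBImage::gblur(uy, 0.75, boundary = "replicate")
  rec <- reconstructTraction(DisplacementGrid(sx, sy, spacing = 8,
                                              unit = "px"), sub)
  expect_lt(abs(max(magnitude(rec)) - 1000) / 1000, 0.2)
})

test_that("degenerate inversion inputs are rejected", {
  sub <- testSubstrate()
  small <- DisplacementGrid(matrix(0, 3, 3), matrix(0, 3, 3), unit = "px")
  expect_error(reconstructTraction(small, sub), "at least 4 x 4")
  bad <- DisplacementGrid(matrix(NA_real_, 8, 8), matrix(0, 8, 8),
                          unit = "px")
  expect_error(reconstructTraction(bad, sub), "non-finite")
  u <- DisplacementGrid(matrix(0, 8, 8), matrix(0, 8, 8), unit = "px")
  expect_error(reconstructTraction(u, sub, lambda = -1), "lambda")
})

test_that("substrate model enforces its physical invariants", {
  expect_error(SubstrateModel(youngModulus = -5), "positive")
  expect_error(SubstrateModel(poissonRatio = 0.7), "0, 0.5")
  expect_error(SubstrateModel(pixelSize = 0), "positive")
  s <- SubstrateModel()
  expect_equal(youngModulus(s), 12000)
  expect_equal(poissonRatio(s), 0.5)
  expect_equal(pixelSize(s), 0.16)
})
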