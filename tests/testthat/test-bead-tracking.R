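test_that("DoG filter is zero on constant images and peaks at spot centres", {
  const <- matrix(7, 64, 64)
  out <- dogFilter(const)
  expect_lt(max(abs(out[9:56, 9:56])), 1e-10)

  # unit impulse: centre value equals the analytic DoG kernel peak
  imp <- matrix(0, 65, 65); imp[33, 33] <- 1
  out <- dogFilter(imp, 1.5, 2.0)
  analytic <- 1 / (2 * pi * 1.5^2) - 1 / (2 * pi * 2^2)
  expect_lt(abs(out[33, 33] - analytic) / analytic, 0.01)

  # Gaussian spot: response maximum sits at the spot centre
  spot <- renderBeads(cbind(20, 30), c(48, 48), psfSigma = 1.5,
                      background = 0.1)
  r <- dogFilter(spot)
  ij <- which(r == max(r), arr.ind = TRUE)
  expect_equal(unname(ij[1, ]), c(30, 20))

  expect_error(dogFilter(const, -1, 2), "positive")
  expect_error(dogFilter(const, 2, 1.5), "smaller")
})

test_that("bead detection localizes well-separated spots to subpixel accuracy", {
  expect_equal(nrow(detectBeads(matrix(5, 64, 64))), 0)

  set.seed(21)
  truth <- cbind(x = c(12.3, 30.7, 50.2, 70.8, 90.4, 15.6, 35.1, 55.9,
                       78.3, 95.5),
                 y = c(14.8, 88.2, 25.4, 60.1, 90.7, 55.3, 15.9, 80.6,
                       40.2, 12.7))
  img <- renderAtSNR(truth, c(108, 108), snr = 20, seed = 4)
  det <- detectBeads(img)
  expect_equal(nrow(det), 10)
  # every truth spot matched within 0.5 px
  for (k in seq_len(nrow(truth))) {
    d <- sqrt((det$x - truth[k, "x"])^2 + (det$y - truth[k, "y"])^2)
    expect_lt(min(d), 0.5)
  }
})

test_that("non-maximum suppression merges spots closer than minDistance", {
  img <- renderBeads(cbind(x = c(30, 32), y = c(30, 30)), c(64, 64),
                     psfSigma = 1.5, background = 0.02)
  det <- detectBeads(img, minDistance = 5)
  expect_equal(nrow(det), 1)
})

test_that("detection count is monotone non-increasing in qualityLevel", {
  set.seed(31)
  pos <- uniformBeads(40, c(128, 128), seed = 31)
  img <- renderAtSNR(pos, c(128, 128), snr = 10, seed = 5)
  counts <- vapply(c(0.02, 0.1, 0.3, 0.6),
                   function(q) nrow(detectBeads(img, qualityLevel = q)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(detectBeads(img, qualityLevel = 1.5), "qualityLevel")
})

test_that("tracking identical images yields zero vectors everywhere", {
  pos <- uniformBeads(60, c(128, 128), seed = 41)
  img <- renderAtSNR(pos, c(128, 128), snr = Inf, seed = 1)
  anchors <- detectBeads(img)
  tr <- trackDisplacements(img, img, anchors, window = 61)
  d <- as.data.frame(tr)
  expect_true(all(d$status == "tracked"))
  expect_lt(max(abs(c(d$dx, d$dy))), 1e-6)
})

test_that("integer circular shifts are recovered to centipixel accuracy", {
  pos <- uniformBeads(100, c(192, 192), seed = 42)
  img <- renderAtSNR(pos, c(192, 192), snr = Inf, seed = 1)
  roll <- function(m, dy, dx) {
    nr <- nrow(m); nc <- ncol(m)
    m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
  }
  loaded <- roll(img, -2, 3)  # content moves by (dx, dy) = (3, -2)
  anchors <- detectBeads(img)
  inner <- anchors[anchors$x > 40 & anchors$x < 152 &
                   anchors$y > 40 & anchors$y < 152, ]
  tr <- as.data.frame(trackDisplacements(img, loaded, inner, window = 61))
  tr <- tr[tr$status == "tracked", ]
  expect_gt(nrow(tr), 10)
  expect_lt(max(abs(tr$dx - 3)), 0.05)
  expect_lt(max(abs(tr$dy + 2)), 0.05)
})

test_that("tracking error decreases with SNR on a smooth warp", {
  dimz <- c(160, 160)
  pos <- uniformBeads(96, dimz, seed = 52)
  d_true <- smoothWarp(pos[, 1], pos[, 2])
  rms <- vapply(c(5, 10, 20), function(snr) {
    rel <- renderAtSNR(pos, dimz, snr, seed = 61)
    lod <- renderAtSNR(pos + d_true, dimz, snr, seed = 62)
    a <- detectBeads(rel)
    t <- as.data.frame(trackDisplacements(rel, lod, a, window = 61))
    td <- smoothWarp(t$x, t$y)
    ok <- t$status == "tracked"
    sqrt(mean((t$dx[ok] - td[ok, 1])^2 + (t$dy[ok] - td[ok, 2])^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
  expect_lt(rms[3], 0.1)
})

test_that("tracking input contracts are enforced", {
  img <- matrix(runif(64^2), 64)
  expect_error(trackDisplacements(img, img[1:32, ], cbind(10, 10)),
               "same shape")
  expect_error(trackDisplacements(img, img, cbind(10, 10)[0, , drop = FALSE]),
               "anchors")
  expect_error(trackDisplacements(img, img, cbind(10, 10), window = 10),
               "odd")
})

test_that("drift correction removes a uniform offset", {
  # all vectors equal, no mask: everything becomes zero
  f <- BeadDisplacements(runif(10, 1, 50), runif(10, 1, 50),
                         rep(1, 10), rep(1, 10))
  fc <- driftCorrect(f)
  expect_equal(max(abs(c(fc@dx, fc@dy))), 0)

  # cell-driven deformation localized inside the mask plus a uniform
  # stage offset: the offset is removed within 0.05 px
  set.seed(9)
  x <- runif(40, 1, 100); y <- runif(40, 1, 100)
  inCell <- (x - 50)^2 + (y - 50)^2 < 15^2
  dx <- ifelse(inCell, 1.2, 0); dy <- ifelse(inCell, -0.8, 0)
  f2 <- BeadDisplacements(x, y, dx + 0.7, dy - 0.3)
  mask <- matrix(FALSE, 100, 100)
  xg <- matrix(1:100, 100, 100, byrow = TRUE)
  yg <- matrix(1:100, 100, 100)
  mask[(xg - 50)^2 + (yg - 50)^2 < 18^2] <- TRUE
  fc2 <- driftCorrect(f2, mask)
  expect_lt(max(abs(fc2@dx[!inCell])), 0.05)
  expect_lt(max(abs(fc2@dy[!inCell])), 0.05)

  # too few reference beads: warning, field unchanged
  f3 <- BeadDisplacements(1:4, 1:4, rep(1, 4), rep(1, 4))
  expect_warning(fc3 <- driftCorrect(f3), "reference beads")
  expect_equal(fc3@dx, f3@dx)
})

test_that("gridding reproduces affine displacement fields exactly", {
  set.seed(17)
  n <- 200
  x <- runif(n, 1, 128); y <- runif(n, 1, 128)
  a <- 0.013; b <- -0.021
  f <- BeadDisplacements(x, y, a * x, b * y)
  g <- gridDisplacements(f, spacing = 8, imageDim = c(128, 128))
  xy <- nodeCoords(g)
  # restrict to nodes well inside the bead cloud's bounding box
  inside <- xy[, "x"] > min(x) + 8 & xy[, "x"] < max(x) - 8 &
            xy[, "y"] > min(y) + 8 & xy[, "y"] < max(y) - 8
  expect_gt(sum(inside), 50)
  expect_lt(max(abs(as.vector(vectorX(g))[inside] -
                    a * xy[inside, "x"])), 1e-6)
  expect_lt(max(abs(as.vector(vectorY(g))[inside] -
                    b * xy[inside, "y"])), 1e-6)
})

test_that("gridding handles constant fields and rejects degenerate input", {
  # beads exactly on grid nodes, constant vector
  gxy <- expand.grid(x = seq(1, 65, 8), y = seq(1, 65, 8))
  f <- BeadDisplacements(gxy$x, gxy$y, rep(1.5, nrow(gxy)),
                         rep(-0.5, nrow(gxy)))
  g <- gridDisplacements(f, spacing = 8, imageDim = c(65, 65))
  expect_equal(max(abs(vectorX(g) - 1.5)), 0, tolerance = 1e-9)
  expect_equal(max(abs(vectorY(g) + 0.5)), 0, tolerance = 1e-9)

  empty <- BeadDisplacements(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_error(gridDisplacements(empty), "4 tracked")
  collinear <- BeadDisplacements(1:10, rep(5, 10), runif(10), runif(10))
  expect_error(gridDisplacements(collinear), "collinear")
})
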