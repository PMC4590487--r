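# Cone catches -----------------------------------------------------------

test_that("von Kries normalization maps flat reflectances to their level", {
  rs <- bluetit_uvs()
  white <- spectrum(300:700, rep(1, 401))
  q <- cone_catch_from_spectrum(white, receptors = rs)
  expect_equal(unname(as.numeric(q)), rep(1, 4), tolerance = 1e-12)
  expect_equal(attr(q, "luminance"), 1, tolerance = 1e-12)

  grey <- spectrum(300:700, rep(0.4, 401))
  q <- cone_catch_from_spectrum(grey, receptors = rs)
  expect_equal(unname(as.numeric(q)), rep(0.4, 4), tolerance = 1e-12)
})

test_that("catch integration agrees with a trapezoid quadrature oracle", {
  rs <- trichromat_visible()
  grid <- 420:680
  set.seed(11)
  for (rep in 1:5) {
    Rv <- runif(length(grid), 0, 1)
    Iv <- runif(length(grid), 0.5, 1.5)
    refl <- spectrum(grid, Rv)
    illum <- spectrum(grid, Iv)
    q <- cone_catch_from_spectrum(refl, illum, rs)
    for (i in seq_along(rs$names)) {
      Sv <- interpolate_spectrum(rs$sensitivities[[i]], grid)$value
      expect_equal(as.numeric(q)[i], oracle_catch_trapz(Rv, Iv, Sv, grid),
                   tolerance = 1e-9)
    }
  }
})

test_that("catches are linear in reflectance before normalization", {
  rs <- trichromat_visible()
  grid <- 420:680
  set.seed(12)
  r1 <- runif(length(grid)); r2 <- runif(length(grid))
  al <- 0.3; be <- 0.6
  q1 <- cone_catch_from_spectrum(spectrum(grid, r1), receptors = rs)
  q2 <- cone_catch_from_spectrum(spectrum(grid, r2), receptors = rs)
  q12 <- cone_catch_from_spectrum(spectrum(grid, al * r1 + be * r2),
                                  receptors = rs)
  # von Kries divides by a reflectance-independent constant, so linearity
  # survives normalization
  expect_equal(as.numeric(q12), al * as.numeric(q1) + be * as.numeric(q2),
               tolerance = 1e-12)
})

# Chromatic JND -----------------------------------------------------------

test_that("chromatic JND matches hand-coded 3- and 4-receptor formulas", {
  set.seed(21)
  e3 <- trich_e
  e4 <- weber_from_abundances(c(UVS = 0.37, SWS = 0.7, MWS = 0.99, LWS = 1),
                              list("LWS", 0.05))
  for (rep in 1:20) {
    qa <- exp(rnorm(4, log(0.3), 0.4)); qb <- exp(rnorm(4, log(0.3), 0.4))
    expect_equal(chromatic_jnd(qa[1:3], qb[1:3], e3),
                 oracle_jnd_trichromat(qa[1:3], qb[1:3], e3),
                 tolerance = 1e-12)
    expect_equal(chromatic_jnd(qa, qb, e4),
                 oracle_jnd_tetrachromat(qa, qb, e4), tolerance = 1e-12)
  }
})

test_that("dichromat reduction has the closed form |df1-df2|/sqrt(e1^2+e2^2)", {
  set.seed(22)
  for (rep in 1:20) {
    qa <- runif(2, 0.05, 1); qb <- runif(2, 0.05, 1)
    e <- runif(2, 0.02, 0.2)
    f <- log(qa / qb)
    expect_equal(chromatic_jnd(qa, qb, e),
                 abs(f[1] - f[2]) / sqrt(e[1]^2 + e[2]^2), tolerance = 1e-12)
  }
})

test_that("chromatic JND is symmetric, zero at equality, intensity-invariant", {
  set.seed(23)
  e <- trich_e
  for (rep in 1:25) {
    qa <- exp(rnorm(3, log(0.3), 0.5)); qb <- exp(rnorm(3, log(0.3), 0.5))
    expect_equal(chromatic_jnd(qa, qb, e), chromatic_jnd(qb, qa, e))
    expect_equal(chromatic_jnd(qa, qa, e), 0)
    k <- exp(rnorm(1))
    expect_equal(chromatic_jnd(k * qa, qa, e), 0, tolerance = 1e-12)
    expect_equal(chromatic_jnd(k * qa, qb, e), chromatic_jnd(qa, qb, e),
                 tolerance = 1e-12)
  }
  expect_error(chromatic_jnd(c(0, 1, 1), c(1, 1, 1), e), "positive")
})

test_that("matrix and scalar chromatic JND agree", {
  set.seed(24)
  Qa <- exp(matrix(rnorm(30, log(0.3), 0.4), 10, 3))
  Qb <- exp(matrix(rnorm(15, log(0.3), 0.4), 5, 3))
  J <- mimicspec:::chromatic_jnd_matrix(Qa, Qb, trich_e)
  for (i in 1:10) for (j in 1:5)
    expect_equal(J[i, j], chromatic_jnd(Qa[i, ], Qb[j, ], trich_e),
                 tolerance = 1e-12)
})

# Luminance JND, Weber scaling --------------------------------------------

test_that("luminance JND has the log-ratio closed form and is symmetric", {
  expect_equal(luminance_jnd(1, 1, 0.05), 0)
  expect_equal(luminance_jnd(exp(0.05), 1, 0.05), 1, tolerance = 1e-12)
  set.seed(25)
  qa <- runif(100, 0.01, 2); qb <- runif(100, 0.01, 2)
  expect_equal(luminance_jnd(qa, qb, 0.07), luminance_jnd(qb, qa, 0.07))
  expect_error(luminance_jnd(-1, 1, 0.05), "positive")
})

test_that("Weber fractions scale with inverse square root of abundance", {
  expect_equal(weber_from_abundances(c(a = 2, b = 2), list("a", 0.05)),
               c(a = 0.05, b = 0.05))
  expect_equal(weber_from_abundances(c(a = 1, b = 4), list("b", 0.05)),
               c(a = 0.10, b = 0.05))
  set.seed(26)
  ab <- setNames(runif(4, 0.2, 2), letters[1:4])
  e <- weber_from_abundances(ab, list("c", 0.08))
  expect_equal(unname(e), 0.08 * sqrt(ab[["c"]] / unname(ab)))
  expect_error(weber_from_abundances(c(a = 0, b = 1), list("b", 0.05)),
               "positive")
})

# Camera-to-cone mapping ---------------------------------------------------

test_that("an exact polynomial relationship is recovered with R^2 = 1", {
  set.seed(31)
  X <- matrix(runif(300, 0.05, 1), 100, 3)
  D <- mimicspec:::poly_design(X, mimicspec:::poly_terms(3, 2))
  B <- matrix(rnorm(ncol(D) * 2, 0, 0.3), ncol(D), 2)
  Y <- D %*% B
  colnames(Y) <- c("r1", "r2")
  map <- fit_camera_to_cone(X, Y, degree = 2)
  expect_true(all(map$fit_r2 >= 1 - 1e-10))
  pred <- apply_camera_to_cone(map, X)
  expect_lt(max(abs(pred - pmax(Y, 1e-6))), 1e-8)
  # prediction at a training point returns the training target
  expect_equal(as.numeric(apply_camera_to_cone(map, X[7, ])),
               as.numeric(pmax(Y[7, ], 1e-6)), tolerance = 1e-8)
})

test_that("matched camera and cone sensitivities give an identity mapping", {
  rs <- trichromat_visible()
  grid <- 420:680
  set.seed(32)
  # library of natural-like reflectances: sums of 1-3 Gaussians
  gen_spec <- function() {
    k <- sample(1:3, 1)
    v <- rep(0.05, length(grid))
    for (i in seq_len(k))
      v <- v + runif(1, 0.1, 0.6) *
        exp(-((grid - runif(1, 430, 670))^2) / (2 * runif(1, 20, 80)^2))
    spectrum(grid, pmin(v, 1.2))
  }
  lib <- replicate(120, gen_spec(), simplify = FALSE)
  cones <- t(vapply(lib, function(s)
    as.numeric(cone_catch_from_spectrum(s, receptors = rs,
                                        include_double_cone = FALSE)),
    numeric(3)))
  colnames(cones) <- rs$names
  map <- fit_camera_to_cone(cones, cones, degree = 1)  # camera == cones
  # degree-1 terms: intercept + 3 channels; coefficient matrix ~ identity
  cf <- map$coefficients
  expect_lt(max(abs(cf[1, ])), 1e-6)                    # intercepts
  expect_equal(unname(cf[2:4, ]), diag(3), tolerance = 1e-6)
})

test_that("degree-2 mapping predicts held-out natural-like spectra well", {
  rs <- trichromat_visible()
  cam <- camera_visible()
  grid <- 420:680
  set.seed(33)
  gen_refl <- function() {
    k <- sample(1:3, 1)
    v <- rep(0.05, length(grid))
    for (i in seq_len(k))
      v <- v + runif(1, 0.1, 0.6) *
        exp(-((grid - runif(1, 430, 670))^2) / (2 * runif(1, 20, 80)^2))
    spectrum(grid, pmin(v, 1.2))
  }
  lib <- replicate(200, gen_refl(), simplify = FALSE)
  cam_rs <- receptor_set(cam, c(vR = 1, vG = 1, vB = 1), list("vR", 0.05))
  cams <- t(vapply(lib, function(s)
    as.numeric(cone_catch_from_spectrum(s, receptors = cam_rs,
                                        include_double_cone = FALSE)),
    numeric(3)))
  cones <- t(vapply(lib, function(s)
    as.numeric(cone_catch_from_spectrum(s, receptors = rs,
                                        include_double_cone = FALSE)),
    numeric(3)))
  colnames(cones) <- rs$names
  train <- 1:140; test <- 141:200
  map <- fit_camera_to_cone(cams[train, ], cones[train, ], degree = 2)
  pred <- apply_camera_to_cone(map, cams[test, ])
  for (j in 1:3) {
    r2 <- 1 - sum((cones[test, j] - pred[, j])^2) /
      sum((cones[test, j] - mean(cones[test, j]))^2)
    expect_gt(r2, 0.95)
  }
  # batch application equals a per-pixel loop
  loop <- t(vapply(test, function(i)
    as.numeric(apply_camera_to_cone(map, cams[i, ])), numeric(3)))
  expect_equal(unname(pred), unname(loop), tolerance = 1e-12)
})

test_that("mapping errors are informative", {
  X <- matrix(runif(60), 20, 3)
  Y <- cbind(rowSums(X))
  expect_error(fit_camera_to_cone(X, Y, degree = 3), "3x more")
  Xc <- cbind(X[, 1], X[, 1], X[, 2])  # collinear channels
  expect_error(fit_camera_to_cone(rbind(Xc, Xc, Xc, Xc), rbind(Y, Y, Y, Y),
                                  degree = 1), "collinear")
  map <- fit_camera_to_cone(X, Y, degree = 1)
  expect_error(apply_camera_to_cone(map, matrix(1, 2, 2)), "channels")
})
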