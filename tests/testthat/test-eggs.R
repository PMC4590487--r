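flat_spec <- function(v, grid = 300:700) spectrum(grid, rep(v, length(grid)))

mk_egg <- function(id, base = 0.3, clutch = "c1", role = "host",
                   jitter = 0, outline = NULL) {
  reps <- lapply(1:5, function(k)
    flat_spec(base * exp(rnorm(1, 0, jitter))))
  egg_record(clutch, id, role, reps, outline)
}

test_that("egg colour/luminance JNDs vanish for an identical egg", {
  set.seed(71)
  clutch <- list(mk_egg("h1"), mk_egg("h2"))
  forn <- mk_egg("x", role = "experimental")
  j <- egg_colour_luminance_jnd(clutch, forn)
  expect_equal(unname(j), c(0, 0), tolerance = 1e-9)
})

test_that("an intensity-only change moves luminance but not colour", {
  clutch <- list(mk_egg("h1", 0.3))
  forn <- mk_egg("x", 0.3 * 1.2, role = "experimental")
  j <- egg_colour_luminance_jnd(clutch, forn)
  expect_equal(j[["colour_jnd"]], 0, tolerance = 1e-9)
  expect_equal(j[["luminance_jnd"]], log(1.2) / 0.05, tolerance = 1e-9)
})

test_that("clutch JNDs match a direct mean-catch formula evaluation", {
  set.seed(72)
  rs <- bluetit_uvs()
  grid <- 300:700
  mk_random <- function(id, role = "host") {
    base <- 0.1 + 0.3 * exp(-((grid - runif(1, 350, 650))^2) / (2 * 60^2))
    reps <- lapply(1:5, function(k)
      spectrum(grid, pmin(base + rnorm(length(grid), 0, 0.005), 1.5) |>
                 pmax(0)))
    egg_record("c", id, role, reps)
  }
  clutch <- list(mk_random("h1"), mk_random("h2"), mk_random("h3"))
  forn <- mk_random("x", "experimental")
  got <- egg_colour_luminance_jnd(clutch, forn, rs)
  qs <- lapply(clutch, function(eg)
    cone_catch_from_spectrum(mean_spectrum(eg$spectra), receptors = rs))
  ref <- rowMeans(vapply(qs, as.numeric, numeric(4)))
  qf <- cone_catch_from_spectrum(mean_spectrum(forn$spectra), receptors = rs)
  e <- weber_fractions(rs)
  expect_equal(got[["colour_jnd"]], chromatic_jnd(as.numeric(qf), ref, e),
               tolerance = 1e-9)
  expect_equal(got[["luminance_jnd"]],
               luminance_jnd(attr(qf, "luminance"),
                             mean(vapply(qs, attr, numeric(1), "luminance")),
                             0.05),
               tolerance = 1e-9)
})

test_that("UVS analyses demand UV coverage in the spectra", {
  vis_only <- lapply(1:5, function(k) flat_spec(0.3, 420:680))
  eg <- egg_record("c", "h", "host", vis_only)
  expect_error(egg_colour_luminance_jnd(list(eg), eg), "UV")
  # the VS system with visible-band coverage down to 420 nm also lacks its
  # 432 nm receptor peak only if spectra start above it
  expect_silent(egg_colour_luminance_jnd(list(eg), eg, peafowl_vs()))
})

test_that("UVS and VS agree loosely when UV reflectance is flat", {
  set.seed(73)
  grid <- 300:700
  mkflat_uv <- function(id, role = "host") {
    v <- 0.25 + 0.25 * stats::plogis((grid - 550) / 60)
    v[grid < 420] <- v[which(grid == 420)]
    reps <- lapply(1:5, function(k) spectrum(grid, v))
    egg_record("c", id, role, reps)
  }
  mk2 <- function(id, role = "host") {
    v <- 0.45 - 0.2 * stats::plogis((grid - 500) / 50)
    v[grid < 420] <- v[which(grid == 420)]
    reps <- lapply(1:5, function(k) spectrum(grid, v))
    egg_record("c", id, role, reps)
  }
  clutch <- list(mkflat_uv("h1"))
  forn <- mk2("x", "experimental")
  uvs <- egg_colour_luminance_jnd(clutch, forn, bluetit_uvs())
  vs <- egg_colour_luminance_jnd(clutch, forn, peafowl_vs())
  expect_gt(uvs[["colour_jnd"]], 0)
  # sanity coupling, not equality
  expect_lt(abs(uvs[["colour_jnd"]] - vs[["colour_jnd"]]) /
              uvs[["colour_jnd"]], 0.35)
})

test_that("shell pattern difference reuses the granularity pipeline", {
  set.seed(74)
  plain <- matrix(0.5, 16, 16)
  spotted <- plain
  spotted[outer(1:16, 1:16, function(r, c) (r %% 6 < 2) & (c %% 6 < 2))] <- 0.2
  expect_equal(egg_pattern_diff(plain, plain), 0)
  expect_gt(egg_pattern_diff(plain, spotted), 0)
  a <- matrix(runif(256), 16, 16); b <- matrix(runif(256), 16, 16)
  expect_equal(egg_pattern_diff(a, b),
               s_diff(pattern_energy(a), pattern_energy(b)))
})

# Volume and shape ---------------------------------------------------------

circle_outline <- function(r = 10, n = 100, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

ellipse_outline <- function(a, b, n = 200, rot = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  cbind(x * cos(rot) - y * sin(rot), x * sin(rot) + y * cos(rot))
}

test_that("a circle revolves to a sphere and an ellipse to a spheroid", {
  v <- egg_volume_shape(circle_outline(10))
  expect_equal(v[["volume_mm3"]], 4 / 3 * pi * 1000, tolerance = 1e-3)
  expect_equal(v[["elongation"]], 1, tolerance = 1e-3)
  expect_equal(v[["asymmetry"]], 0, tolerance = 0.01)

  v2 <- egg_volume_shape(ellipse_outline(25, 15))
  expect_equal(v2[["volume_mm3"]], 4 / 3 * pi * 25 * 15^2, tolerance = 1e-3)
  expect_equal(v2[["elongation"]], 25 / 15, tolerance = 1e-3)
})

test_that("volume is rigid-motion invariant and scales as k^3", {
  set.seed(75)
  ov <- mimicspec:::egg_outline(16, 12, 0.15)
  base <- egg_volume_shape(ov)
  rot <- 0.7
  Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  moved <- ov %*% Rm + matrix(c(5, -3), nrow(ov), 2, byrow = TRUE)
  expect_equal(egg_volume_shape(moved)[["volume_mm3"]], base[["volume_mm3"]],
               tolerance = 1e-3)
  scaled <- egg_volume_shape(ov * 1.3)
  expect_equal(scaled[["volume_mm3"]], base[["volume_mm3"]] * 1.3^3,
               tolerance = 1e-3)
  expect_equal(scaled[["elongation"]], base[["elongation"]], tolerance = 1e-9)
})

test_that("ovoid volume matches a fine voxel-revolution oracle", {
  ov <- mimicspec:::egg_outline(15.5, 11.5, 0.12, n = 256)
  got <- egg_volume_shape(ov, n_profile = 2000)[["volume_mm3"]]
  # oracle: stack thin axial discs with radius from the parametric width
  u <- seq(-1, 1, length.out = 20001)
  w <- (11.5 / 2) * sqrt(pmax(1 - u^2, 0)) / (1 + 0.12 * u)
  x <- (15.5 / 2) * u
  oracle <- pi * sum(w[-1]^2 * diff(x))
  expect_lt(abs(got - oracle) / oracle, 0.005)
})

test_that("degenerate outlines are rejected", {
  expect_error(egg_volume_shape(circle_outline(10, n = 10)), "20 points")
  bow <- cbind(c(0, 10, 0, 10, seq(8, 2, length.out = 18)),
               c(0, 10, 10, 0, rep(-2, 18)))
  expect_error(egg_volume_shape(bow), "self-intersecting")
})

# Outcome classification ---------------------------------------------------

test_that("nest-check classification follows the field decision rules", {
  # one egg gone at day 2 -> rejected
  r <- classify_outcome(data.frame(day = 1:2, n_eggs = c(4, 3),
                                   incubating = TRUE), 4)
  expect_equal(as.character(r), "rejected")
  # intact and incubating through day 3 -> accepted
  expect_equal(classify_outcome(data.frame(day = 1:3, n_eggs = 4,
                                           incubating = TRUE), 4), "accepted")
  # whole clutch gone -> depredated
  expect_equal(classify_outcome(data.frame(day = 2, n_eggs = 0,
                                           incubating = FALSE), 4),
               "depredated")
  # intact but never confirmed to day 3 -> unresolved
  expect_equal(classify_outcome(data.frame(day = 1:2, n_eggs = 4,
                                           incubating = TRUE), 4),
               "unresolved")
  # two eggs missing is not single-egg rejection
  expect_equal(classify_outcome(data.frame(day = 1, n_eggs = 2,
                                           incubating = TRUE), 4),
               "unresolved")
  # the identity of the missing egg is flagged when recorded
  r2 <- classify_outcome(data.frame(day = 1, n_eggs = 3, incubating = TRUE,
                                    experimental_present = FALSE), 4)
  expect_equal(attr(r2, "rejected_egg"), "experimental")
  expect_error(classify_outcome(data.frame(day = 1, n_eggs = 5,
                                           incubating = TRUE), 4),
               "increased")
})
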