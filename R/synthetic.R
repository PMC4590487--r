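#' Derive a child seed from a top-level seed
#'
#' Splittable counter scheme: every generator component draws its own seed
#' from the run seed and a stable string key, so adding a new component
#' never perturbs the streams of existing ones. Results stay below 2^31.
#'
#' @param seed Integer top-level seed.
#' @param key Component name.
#' @param index Optional replicate counter.
#' @return Integer seed.
#' @export
child_seed <- function(seed, key, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 48271 + h + index * 10007) %% 2147483629) + 1L
}

# --- specimen generator -----------------------------------------------------

#' Define a synthetic taxon
#'
#' One taxon of the museum-skin emulation: its chromatic locus offset (in
#' log cone-catch space, relative to the focal mimic), pattern profile and
#' sample size.
#'
#' @param name Taxon label.
#' @param group One of `focal_mimic`, `conspecific_male`, `model_group`,
#'   `relative_group`.
#' @param colour_offset Length-3 offset (log catch, SWS/MWS/LWS) from the
#'   mimic's locus.
#' @param pattern_peak_px Dominant marking scale of the plumage texture.
#' @param pattern_contrast Texture contrast (sd of the luminance noise).
#' @param n_specimens Skins per taxon, default 8.
#' @param within_sd Specimen-to-specimen scatter of the log chromatic
#'   locus.
#' @param within_lum_sd Specimen-to-specimen scatter of log luminance.
#' @param pixel_sd Pixel-level chromatic scatter (log catch).
#' @return Object of class `"taxon_spec"`.
#' @export
taxon_spec <- function(name, group = c("focal_mimic", "conspecific_male",
                                       "model_group", "relative_group"),
                       colour_offset = c(0, 0, 0),
                       pattern_peak_px = 6, pattern_contrast = 0.06,
                       n_specimens = 8, within_sd = 0.02,
                       within_lum_sd = 0.034, pixel_sd = 0.05) {
  group <- match.arg(group)
  if (n_specimens < 2) stop("need at least 2 specimens per taxon")
  structure(list(name = name, group = group,
                 colour_offset = as.numeric(colour_offset),
                 pattern_peak_px = pattern_peak_px,
                 pattern_contrast = pattern_contrast,
                 n_specimens = n_specimens, within_sd = within_sd,
                 within_lum_sd = within_lum_sd, pixel_sd = pixel_sd),
            class = "taxon_spec")
}

# Chromatic JND of a log-catch displacement v under Weber fractions e;
# linear in ||v||, used to calibrate taxon separations.
jnd_of_direction <- function(v, e) chromatic_jnd(exp(v), rep(1, length(v)), e)

# Base chromatic locus of the focal mimic (tawny/brown, SWS/MWS/LWS) and
# fixed per-region displacements shared by all taxa, so regions differ in
# colour while inter-taxon separations stay constant across regions.
.mimic_base_locus <- c(SWS = 0.18, MWS = 0.28, LWS = 0.38)

.region_table <- data.frame(
  region = BODY_REGIONS,
  dl1 = c(0.05, -0.30, 0.25, 0.20, 0.10, 0.30, 0.00, 0.28, -0.10),
  dl2 = c(0.00, -0.35, 0.20, 0.12, 0.05, 0.22, -0.05, 0.20, -0.15),
  dl3 = c(-0.05, -0.25, 0.10, 0.05, 0.00, 0.10, -0.08, 0.12, -0.20),
  base_lum = c(0.30, 0.18, 0.45, 0.40, 0.35, 0.50, 0.28, 0.48, 0.25),
  peak_mult = c(1.0, 0.6, 1.2, 1.0, 0.8, 0.7, 0.9, 1.1, 1.4))

#' Default taxon set calibrated to the study's separations
#'
#' Four taxa — the focal mimic, its conspecific male, the model group
#' (*Euplectes*-like) and the relative group (*Vidua*-like) — whose
#' chromatic loci are placed so the locus-to-locus JNDs from the mimic are
#' close to the study's group means (2.86, 3.92 and 8.17 JND to model,
#' relative and conspecific male respectively, under the trichromatic
#' Weber fractions). The mimic, model and conspecific male share a texture
#' profile; the relative group is finer-grained and higher contrast, so
#' pattern difference separates the relative group only.
#'
#' @param e Chromatic Weber fractions used for calibration; default the
#'   trichromatic skin set.
#' @param jnd_model,jnd_relative,jnd_male Target locus separations (JND).
#' @param n_specimens Skins per taxon, default 8.
#' @return Named list of [taxon_spec()]s.
#' @export
default_taxa <- function(e = weber_from_abundances(
                           c(SWS = 0.70, MWS = 0.99, LWS = 1.00),
                           list("LWS", 0.05)),
                         jnd_model = 2.86, jnd_relative = 3.92,
                         jnd_male = 8.17, n_specimens = 8) {
  calib <- function(dir, target) dir * (target / jnd_of_direction(dir, e))
  d_model <- c(0.5, -0.2, -0.3)
  d_rel <- c(-0.6, 0.8, -0.2)
  d_male <- c(0.9, -0.1, -0.8)
  list(
    mimic = taxon_spec("cuckoo_finch_female", "focal_mimic",
                       n_specimens = n_specimens),
    conspecific_male = taxon_spec("cuckoo_finch_male", "conspecific_male",
                                  colour_offset = calib(d_male, jnd_male),
                                  n_specimens = n_specimens),
    model_group = taxon_spec("Euplectes", "model_group",
                             colour_offset = calib(d_model, jnd_model),
                             n_specimens = n_specimens),
    relative_group = taxon_spec("Vidua", "relative_group",
                                colour_offset = calib(d_rel, jnd_relative),
                                pattern_peak_px = 3, pattern_contrast = 0.12,
                                n_specimens = n_specimens))
}

# Band-limited noise: white noise shaped in the Fourier domain by a
# Gaussian amplitude profile (half-octave width) around the peak spatial
# scale, rescaled to the requested contrast (sd).
shaped_noise <- function(dim, peak_px, contrast) {
  z <- matrix(stats::rnorm(dim * dim), dim, dim)
  fr <- sqrt(outer(fft_freq(dim)^2, fft_freq(dim)^2, "+"))
  amp <- exp(-((log2(pmax(fr, 1e-6)) - log2(1 / peak_px))^2) / (2 * 0.5^2))
  amp[1, 1] <- 0
  filt <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / (dim * dim)
  s <- stats::sd(filt)
  if (s == 0) return(matrix(0, dim, dim))
  filt * (contrast / s)
}

#' Generate a synthetic museum-skin specimen set
#'
#' Emulates the study design: `n_specimens` skins per taxon, nine body
#' regions per skin. Each region patch is a set of pixel cone catches with
#' lognormal scatter around the taxon-region chromatic locus, and a
#' luminance grid whose texture is band-limited noise shaped to the
#' taxon's pattern profile. The ground-truth table records the true
#' locus-to-locus JND separations behind the data.
#'
#' @param taxa Named list of [taxon_spec()]s; the entry with group
#'   `focal_mimic` is the focal taxon. Default [default_taxa()].
#' @param seed Integer seed; all randomness is derived from it.
#' @param grid_dim Side of the square luminance grid per patch (pixel
#'   count is `grid_dim^2`, kept within the 2000-pixel analysis budget at
#'   the default 44).
#' @param e Chromatic Weber fractions (for ground-truth JNDs only).
#' @return List: `focal` (specimen list), `others` (specimen lists named
#'   by comparison group: `conspecific_male`, `Euplectes`, `Vidua`),
#'   `ground_truth` (data frame), `taxa`.
#' @export
generate_specimens <- function(taxa = default_taxa(), seed = 1L,
                               grid_dim = 44,
                               e = weber_from_abundances(
                                 c(SWS = 0.70, MWS = 0.99, LWS = 1.00),
                                 list("LWS", 0.05))) {
  if (grid_dim^2 > 2000)
    stop("grid_dim^2 exceeds the 2000-pixel analysis budget")
  base_log <- log(.mimic_base_locus)
  gen_taxon <- function(ts) {
    withr::with_seed(child_seed(seed, paste0("specimens/", ts$name)), {
      lapply(seq_len(ts$n_specimens), function(i) {
        patches <- list()
        for (r in seq_len(nrow(.region_table))) {
          rg <- .region_table$region[r]
          reg_off <- as.numeric(.region_table[r, c("dl1", "dl2", "dl3")])
          locus <- base_log + reg_off + ts$colour_offset +
            stats::rnorm(3, 0, ts$within_sd)
          n <- grid_dim^2
          catches <- exp(matrix(locus, n, 3, byrow = TRUE) +
                           matrix(stats::rnorm(n * 3, 0, ts$pixel_sd), n, 3))
          colnames(catches) <- names(.mimic_base_locus)
          lum0 <- .region_table$base_lum[r] *
            exp(stats::rnorm(1, 0, ts$within_lum_sd))
          grid <- lum0 + shaped_noise(grid_dim,
                                      ts$pattern_peak_px * .region_table$peak_mult[r],
                                      ts$pattern_contrast * lum0)
          grid <- pmax(grid, 1e-4)
          patches[[rg]] <- cone_catch_patch(catches, as.vector(grid), rg,
                                            grid = grid)
        }
        list(id = sprintf("%s_%02d", ts$name, i), patches = patches)
      })
    })
  }
  groups <- vapply(taxa, function(t) t$group, character(1))
  focal_ts <- taxa[[which(groups == "focal_mimic")[1]]]
  focal <- gen_taxon(focal_ts)
  label <- c(conspecific_male = "conspecific_male", model_group = "Euplectes",
             relative_group = "Vidua")
  others <- list()
  gt <- list()
  for (ts in taxa) {
    if (ts$group == "focal_mimic") next
    others[[label[[ts$group]]]] <- gen_taxon(ts)
    gt[[length(gt) + 1L]] <- data.frame(
      taxon = ts$name, group = label[[ts$group]],
      true_colour_jnd = jnd_of_direction(ts$colour_offset - focal_ts$colour_offset, e),
      pattern_peak_px = ts$pattern_peak_px,
      pattern_contrast = ts$pattern_contrast)
  }
  list(focal = focal, others = others, ground_truth = do.call(rbind, gt),
       taxa = taxa)
}

# --- egg-rejection experiment generator -------------------------------------

#' Specify a synthetic experiment
#'
#' Dimensions and effect sizes of the behavioural emulation. Defaults
#' mirror the study: rejection arms of 17/16/18 pairs with marginal
#' rejection rates 58.2%, 62.5% and 38.9%; a colour-difference effect of
#' 0.29 per JND on the rejection log-odds; and 15 pairs x 4 model types
#' for the aggression experiment.
#'
#' @param arms Named integer vector of rejection-arm sizes.
#' @param arm_rejection_probs Marginal rejection probability per arm.
#' @param colour_jnd_effect Log-odds slope on egg colour JND.
#' @param n_pairs Pairs in the aggression experiment.
#' @param alarm_means,mobbing_means Named per-model-type means (counts per
#'   300 s; seconds of 300).
#' @param alarm_size Negative-binomial size (dispersion) of alarm counts.
#' @param pair_sd_log_alarm Pair random intercept sd on the log alarm
#'   scale.
#' @param mobbing_pair_sd,mobbing_resid_sd Pair and residual sd of
#'   mobbing seconds (censored to \[0, 300\]).
#' @param n_host_eggs Host eggs per clutch.
#' @param seed Integer seed.
#' @return Object of class `"experiment_spec"`.
#' @export
experiment_spec <- function(
    arms = c(female_cuckoo_finch = 17, female_bishop = 16, male_bishop = 18),
    arm_rejection_probs = c(female_cuckoo_finch = 0.582,
                            female_bishop = 0.625, male_bishop = 0.389),
    colour_jnd_effect = 0.29,
    n_pairs = 15,
    alarm_means = c(female_cuckoo_finch = 30, male_cuckoo_finch = 10,
                    female_bishop = 30, male_bishop = 8),
    mobbing_means = c(female_cuckoo_finch = 120, male_cuckoo_finch = 40,
                      female_bishop = 120, male_bishop = 30),
    alarm_size = 3, pair_sd_log_alarm = 0.3,
    mobbing_pair_sd = 25, mobbing_resid_sd = 40,
    n_host_eggs = 3, seed = 1L) {
  if (any(arm_rejection_probs < 0 | arm_rejection_probs > 1))
    stop("arm rejection probabilities must lie in [0, 1]")
  if (any(arms < 1)) stop("arm sizes must be >= 1")
  structure(list(arms = arms, arm_rejection_probs = arm_rejection_probs,
                 colour_jnd_effect = colour_jnd_effect, n_pairs = n_pairs,
                 alarm_means = alarm_means, mobbing_means = mobbing_means,
                 alarm_size = alarm_size,
                 pair_sd_log_alarm = pair_sd_log_alarm,
                 mobbing_pair_sd = mobbing_pair_sd,
                 mobbing_resid_sd = mobbing_resid_sd,
                 n_host_eggs = n_host_eggs, seed = seed),
            class = "experiment_spec")
}

# Polymorphic egg ground-colour family: a low plateau plus a blue-green
# Gaussian bump, a long-wave sigmoid shoulder (olive/brown morphs) and a
# small UV component. Column-per-egg reflectance matrix on `grid`.
egg_reflectance_matrix <- function(pars, grid = 300:700) {
  n <- nrow(pars)
  R <- matrix(0, length(grid), n)
  for (i in seq_len(n)) {
    v <- pars$base[i] +
      pars$a_blue[i] * exp(-((grid - pars$mu_blue[i])^2) / (2 * 45^2)) +
      pars$a_brown[i] * stats::plogis((grid - 560) / 40) +
      pars$a_uv[i] * exp(-((grid - 350)^2) / (2 * 30^2))
    R[, i] <- pmin(pmax(v, 0.02), 1.2)
  }
  R
}

# Draw clutch-level ground-colour parameters from the polymorphic mixture.
draw_egg_params <- function(n) {
  data.frame(base = stats::runif(n, 0.10, 0.45),
             a_blue = stats::runif(n, 0, 0.35),
             mu_blue = stats::runif(n, 440, 520),
             a_brown = stats::runif(n, 0, 0.40),
             a_uv = stats::runif(n, 0, 0.15))
}

jitter_params <- function(pars, sd = 0.02) {
  for (cc in names(pars)) pars[[cc]] <- pars[[cc]] * exp(stats::rnorm(nrow(pars), 0, sd))
  pars$mu_blue <- pmin(pmax(pars$mu_blue, 430), 530)
  pars
}

# Interpolated sensitivity matrix (wavelengths x receptors+DBL), hoisted
# out of per-clutch loops.
sensitivity_matrix <- function(receptors, grid = 300:700) {
  S <- vapply(c(receptors$sensitivities, list(DBL = receptors$double_cone)),
              function(s) interpolate_spectrum(s, grid)$value,
              numeric(length(grid)))
  colnames(S) <- c(receptors$names, "DBL")
  S
}

# Fast vectorized catches for a reflectance matrix: columns are eggs.
# Equivalent to cone_catch_from_spectrum under a flat illuminant (the
# equivalence is pinned by a unit test).
catch_matrix <- function(R, receptors, grid = 300:700, S = NULL) {
  if (is.null(S)) S <- sensitivity_matrix(receptors, grid)
  Sw <- S * c(0.5, rep(1, nrow(S) - 2), 0.5)  # trapezoid weights
  t(Sw) %*% R / colSums(Sw)  # von Kries: denominator = catch of R == 1
}

# Calibrate the arm intercept so the marginal rejection rate equals p
# under slope beta and the supplied colour-JND sample.
calibrate_alpha <- function(p, beta, jnd_sample) {
  if (p <= 0 || p >= 1) {
    if (beta != 0)
      stop("uncalibratable arm: marginal rate 0 or 1 with a nonzero slope")
    return(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)))
  }
  if (beta == 0) return(stats::qlogis(p))
  f <- function(a) mean(stats::plogis(a + beta * jnd_sample)) - p
  stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
}

# Parametric ovoid outline: length L, max width W, asymmetry T.
egg_outline <- function(L, W, T_asym, n = 64) {
  u <- cos(seq(0, pi, length.out = n %/% 2 + 1))  # 1 -> -1
  w <- (W / 2) * sqrt(pmax(1 - u^2, 0)) / (1 + T_asym * u)
  x <- (L / 2) * u
  cbind(x_mm = c(x, rev(x)[-1][-(n %/% 2)]),
        y_mm = c(w, -rev(w)[-1][-(n %/% 2)]))
}

#' Generate a synthetic egg-rejection experiment
#'
#' Emulates the coupled model-presentation / egg-rejection design: each
#' breeding pair sees one model type, its clutch receives one experimental
#' conspecific egg, and the rejection outcome follows
#' `Bernoulli(plogis(alpha_arm + beta * colour_jnd))`, with each arm's
#' intercept calibrated so the marginal rejection rate equals the
#' specified arm rate. Host clutches draw their ground colour from a
#' polymorphic mixture spanning blue-white to olive; the experimental egg
#' is an independent draw from the same population, so colour differences
#' range from mimetic to non-mimetic.
#'
#' @param spec An [experiment_spec()].
#' @param receptors Tetrachromatic [receptor_set()] for egg JNDs, default
#'   [bluetit_uvs()].
#' @param full_artifacts If `TRUE` (default) also build per-egg
#'   [egg_record()]s (5 replicate spectra each), outlines, shell pattern
#'   patches and nest-check tables, and compute the pattern/shape/volume
#'   covariates through the image pipeline. `FALSE` is a fast path for
#'   replicate calibration studies: outcomes and colour/luminance JNDs
#'   are computed identically, the artifact covariates are skipped.
#' @param seed Optional seed override (defaults to `spec$seed`).
#' @return List: `rejection_table` (one row per pair), `eggs` (list of
#'   clutches), `nest_checks` (data frame), `ground_truth` (calibrated
#'   intercepts and the slope).
#' @export
generate_egg_experiment <- function(spec = experiment_spec(),
                                    receptors = bluetit_uvs(),
                                    full_artifacts = TRUE, seed = NULL) {
  seed <- if (is.null(seed)) spec$seed else seed
  grid <- 300:700
  beta <- spec$colour_jnd_effect
  e <- weber_fractions(receptors)
  e_D <- receptors$double_cone_weber
  S <- sensitivity_matrix(receptors, grid)
  chrom <- receptors$names
  nh <- spec$n_host_eggs

  # JND reference sample for intercept calibration (own child stream)
  jnd_sample <- NULL
  if (beta != 0) {
    jnd_sample <- withr::with_seed(child_seed(seed, "egg/calibration"), {
      m <- 400
      host <- draw_egg_params(m); forn <- draw_egg_params(m)
      Qh <- catch_matrix(egg_reflectance_matrix(host, grid), receptors, grid, S)
      Qf <- catch_matrix(egg_reflectance_matrix(forn, grid), receptors, grid, S)
      vapply(seq_len(m), function(i)
        chromatic_jnd(Qf[chrom, i], Qh[chrom, i], e), numeric(1))
    })
  }
  alphas <- vapply(names(spec$arms), function(a)
    calibrate_alpha(spec$arm_rejection_probs[[a]], beta, jnd_sample),
    numeric(1))

  rows <- list(); clutches <- list(); checks <- list()
  pair0 <- 0L
  for (arm in names(spec$arms)) {
    n_arm <- spec$arms[[arm]]
    withr::with_seed(child_seed(seed, paste0("egg/arm/", arm)), {
      # clutch-level draws, per-egg jitter within clutch, one independent
      # experimental egg per clutch; all catches in one matrix product
      host_pars <- jitter_params(
        draw_egg_params(n_arm)[rep(seq_len(n_arm), each = nh), , drop = FALSE])
      foreign_pars <- draw_egg_params(n_arm)
      Rh <- egg_reflectance_matrix(host_pars, grid)
      Rf <- egg_reflectance_matrix(foreign_pars, grid)
      Qh <- catch_matrix(Rh, receptors, grid, S)
      Qf <- catch_matrix(Rf, receptors, grid, S)
      cj <- lj <- numeric(n_arm)
      for (i in seq_len(n_arm)) {
        cols <- (i - 1L) * nh + seq_len(nh)
        ref <- rowMeans(Qh[chrom, cols, drop = FALSE])
        cj[i] <- chromatic_jnd(Qf[chrom, i], ref, e)
        lj[i] <- luminance_jnd(Qf["DBL", i], mean(Qh["DBL", cols]), e_D)
      }
      rejected <- stats::runif(n_arm) < stats::plogis(alphas[[arm]] + beta * cj)

      pat_diff <- shp_diff <- vol_diff <- rep(NA_real_, n_arm)
      pids <- sprintf("pair_%03d", pair0 + seq_len(n_arm))
      if (full_artifacts) {
        for (i in seq_len(n_arm)) {
          pid <- pids[i]
          # per-egg artifacts: replicate spectra, outlines, shell texture
          mk_egg <- function(refl, j, role) {
            reps <- lapply(seq_len(5), function(k) {
              v <- refl * exp(stats::rnorm(1, 0, 0.01)) +
                stats::rnorm(length(grid), 0, 0.004)
              spectrum(grid, pmin(pmax(v, 0), 1.5))
            })
            L <- stats::rnorm(1, 15.5, 0.5); W <- stats::rnorm(1, 11.5, 0.4)
            Ta <- stats::rnorm(1, 0.12, 0.03)
            shell <- matrix(0.5, 16, 16) +
              shaped_noise(16, stats::runif(1, 2.5, 5), stats::runif(1, 0.02, 0.12))
            egg_record(pid, sprintf("%s_egg%d", pid, j),
                       role, reps, egg_outline(L, W, Ta), shell)
          }
          cols <- (i - 1L) * nh + seq_len(nh)
          eggs <- c(lapply(seq_len(nh), function(j)
                      mk_egg(Rh[, cols[j]], j, "host")),
                    list(mk_egg(Rf[, i], nh + 1L, "experimental")))
          clutches[[pid]] <- eggs
          host_eggs <- eggs[seq_len(nh)]
          forn_egg <- eggs[[nh + 1]]
          pat_host <- Reduce(`+`, lapply(host_eggs, `[[`, "pattern_patch")) / nh
          pat_diff[i] <- egg_pattern_diff(pat_host, forn_egg$pattern_patch)
          vs_host <- lapply(host_eggs, function(eg) egg_volume_shape(eg$outline))
          vs_forn <- egg_volume_shape(forn_egg$outline)
          vol_diff[i] <- abs(vs_forn[["volume_mm3"]] -
                               mean(vapply(vs_host, `[[`, numeric(1), "volume_mm3")))
          shp_diff[i] <- egg_shape_diff(vs_forn, Reduce(`+`, vs_host) / nh,
                                        scale = c(0.2, 0.05))
          # nest checks consistent with the outcome classification rules
          nc <- nh + 1L
          checks[[pid]] <- if (rejected[i]) data.frame(
            clutch_id = pid, day = 1:2, n_eggs = c(nc, nc - 1L),
            incubating = c(TRUE, TRUE))
          else data.frame(clutch_id = pid, day = 1:3, n_eggs = nc,
                          incubating = TRUE)
        }
      }
      rows[[arm]] <- data.frame(
        pair_id = pids, model_type = arm, colour_jnd = cj,
        luminance_jnd = lj, pattern_diff = pat_diff, shape_diff = shp_diff,
        volume_diff = vol_diff,
        outcome = as.integer(rejected), stringsAsFactors = FALSE)
      pair0 <- pair0 + n_arm
    })
  }
  list(rejection_table = do.call(rbind, rows),
       eggs = clutches,
       nest_checks = if (length(checks)) do.call(rbind, checks) else NULL,
       ground_truth = list(alphas = alphas, beta = beta,
                           arm_rejection_probs = spec$arm_rejection_probs))
}

# --- aggression-trial generator ---------------------------------------------

#' Generate synthetic model-presentation trials
#'
#' Emulates the nest-defence experiment: each pair experiences all four
#' model types in a randomized order on one day, with the model replicate
#' swapped between trials. Alarm-call counts are negative binomial and
#' mobbing seconds censored Gaussian around the per-model-type means, both
#' with a pair-level random intercept. Order, replicate and nest-stage
#' effects are zero by construction (they are candidate terms the
#' elimination stage should drop).
#'
#' @param spec An [experiment_spec()].
#' @param seed Optional seed override.
#' @return Data frame of trial records (one row per pair x model type).
#' @export
generate_aggression_trials <- function(spec = experiment_spec(), seed = NULL) {
  seed <- if (is.null(seed)) spec$seed else seed
  types <- names(spec$alarm_means)
  withr::with_seed(child_seed(seed, "aggression"), {
    rows <- list()
    for (p in seq_len(spec$n_pairs)) {
      ord <- sample(types)
      stage <- sample(c("laying", "early_incubation"), 1)
      rep_start <- sample(0:1, 1)  # replicate swapped between trials
      u_alarm <- stats::rnorm(1, 0, spec$pair_sd_log_alarm)
      u_mob <- stats::rnorm(1, 0, spec$mobbing_pair_sd)
      for (k in seq_along(ord)) {
        ty <- ord[k]
        mu_a <- spec$alarm_means[[ty]] * exp(u_alarm)
        alarm <- stats::rnbinom(1, size = spec$alarm_size, mu = mu_a)
        mob <- stats::rnorm(1, spec$mobbing_means[[ty]] + u_mob,
                            spec$mobbing_resid_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = sprintf("pair_%02d", p), model_type = ty,
          presentation_order = k,
          model_replicate = 1L + (rep_start + k) %% 2L,
          nest_stage = stage, alarm_calls = alarm,
          mobbing_seconds = min(300, max(0, mob)),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
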