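# Shared fixtures and independent oracles used across test files.

trich_e <- weber_from_abundances(c(SWS = 0.70, MWS = 0.99, LWS = 1.00),
                                 list("LWS", 0.05))

# Direct transcription of the receptor-noise formulas, kept deliberately
# separate from the package's general-n implementation.
oracle_jnd_trichromat <- function(qa, qb, e) {
  qa <- unname(qa); qb <- unname(qb); e <- unname(e)
  f <- log(qa / qb)
  num <- e[1]^2 * (f[3] - f[2])^2 + e[2]^2 * (f[3] - f[1])^2 +
    e[3]^2 * (f[2] - f[1])^2
  den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  sqrt(num / den)
}

oracle_jnd_tetrachromat <- function(qa, qb, e) {
  qa <- unname(qa); qb <- unname(qb); e <- unname(e)
  f <- log(qa / qb)
  num <- (e[1] * e[2])^2 * (f[4] - f[3])^2 +
    (e[1] * e[3])^2 * (f[4] - f[2])^2 +
    (e[1] * e[4])^2 * (f[3] - f[2])^2 +
    (e[2] * e[3])^2 * (f[4] - f[1])^2 +
    (e[2] * e[4])^2 * (f[3] - f[1])^2 +
    (e[3] * e[4])^2 * (f[2] - f[1])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
    (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  sqrt(num / den)
}

# Brute-force abundant colour: per-pixel loop over scalar JND calls.
oracle_abundant_colour <- function(Q, e, radius = 2) {
  n <- nrow(Q)
  counts <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      if (oracle_jnd_trichromat(Q[i, ], Q[j, ], e) < radius) cnt <- cnt + 1L
    }
    counts[i] <- cnt
  }
  best <- which.max(counts)
  list(pixel = best, count = counts[best])
}

# Random cone-catch patch around a lognormal colour cloud.
random_patch <- function(n, k = 3, sd = 0.3, region = "back") {
  mu <- log(runif(k, 0.15, 0.6))
  Q <- exp(matrix(mu, n, k, byrow = TRUE) + matrix(rnorm(n * k, 0, sd), n, k))
  cone_catch_patch(Q, exp(rnorm(n, log(0.3), 0.2)), region)
}

# Log density of N(0, V), written out to stay independent of the fitters.
mvtnorm_dmvnorm <- function(resid, V) {
  L <- chol(V)
  z <- backsolve(L, resid, transpose = TRUE)
  -0.5 * (length(resid) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# Trapezoid-rule quantum catch, independent of the package's summation.
oracle_catch_trapz <- function(R, I, S, grid) {
  f <- R * I * S
  num <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
  g <- I * S
  den <- sum((g[-1] + g[-length(g)]) / 2 * diff(grid))
  num / den
}
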