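#' Receptor-noise-limited chromatic discrimination (JND)
#'
#' Perceptual distance between two stimuli in units of just-noticeable
#' differences under the receptor-noise-limited model. Works for any number
#' of chromatic receptors >= 2; for a trichromat and tetrachromat this is
#' the familiar closed form, and for a dichromat it reduces to
#' `|df1 - df2| / sqrt(e1^2 + e2^2)`.
#'
#' The contrast in receptor i is `df_i = ln(qa_i / qb_i)` (Fechnerian log
#' contrast of von Kries-normalized catches), and
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} (\prod_{k \ne i,j} e_k)^2 (df_i - df_j)^2}
#'                         {\sum_i (\prod_{k \ne i} e_k)^2}}
#' which makes the distance invariant to scaling either stimulus by a
#' positive constant (intensity is discounted; only catch ratios matter).
#'
#' @param qa,qb Positive catch vectors over the same receptors (named or
#'   positional, length 2-4+).
#' @param e Weber fractions per receptor (same length/order).
#' @return Non-negative JND (dimensionless scalar).
#' @export
chromatic_jnd <- function(qa, qb, e) {
  qa <- as.numeric(qa); qb <- as.numeric(qb); e <- as.numeric(e)
  n <- length(e)
  if (length(qa) != n || length(qb) != n)
    stop("catch vectors and Weber fractions must cover the same receptors")
  if (n < 2) stop("need at least 2 chromatic receptors")
  if (any(qa <= 0) || any(qb <= 0)) stop("cone catches must be positive")
  if (any(e <= 0)) stop("Weber fractions must be positive")
  df <- log(qa / qb)
  num <- 0
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    w <- prod(e[-c(i, j)])^2
    num <- num + w * (df[i] - df[j])^2
  }
  den <- sum(vapply(seq_len(n), function(i) prod(e[-i])^2, numeric(1)))
  sqrt(num / den)
}

# Vectorised pairwise chromatic JND between the rows of two catch
# matrices (m x n_receptors and k x n_receptors): returns an m x k matrix.
# Same model as chromatic_jnd; kept in matrix form for the exhaustive
# abundant-colour search over patch pixels.
chromatic_jnd_matrix <- function(Qa, Qb, e) {
  Qa <- as.matrix(Qa); Qb <- as.matrix(Qb)
  n <- length(e)
  stopifnot(ncol(Qa) == n, ncol(Qb) == n)
  if (any(Qa <= 0) || any(Qb <= 0)) stop("cone catches must be positive")
  La <- log(Qa); Lb <- log(Qb)
  num <- matrix(0, nrow(Qa), nrow(Qb))
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    # (df_i - df_j) = (La_i - La_j) - (Lb_i - Lb_j): outer difference
    da <- La[, i] - La[, j]
    db <- Lb[, i] - Lb[, j]
    d <- outer(da, db, "-")
    num <- num + (prod(e[-c(i, j)])^2) * d * d
  }
  den <- sum(vapply(seq_len(n), function(i) prod(e[-i])^2, numeric(1)))
  sqrt(num / den)
}

#' Achromatic (luminance) discrimination
#'
#' JND between two double-cone catches under Weber's law on log contrast:
#' `|ln(qa/qb)| / e_D`.
#'
#' @param qa,qb Positive double-cone catches.
#' @param e_D Weber fraction of the achromatic channel, in (0, 1).
#' @return Non-negative JND; vectorised over `qa`/`qb`.
#' @export
luminance_jnd <- function(qa, qb, e_D = 0.05) {
  if (any(qa <= 0) || any(qb <= 0)) stop("cone catches must be positive")
  if (e_D <= 0 || e_D >= 1) stop("e_D must lie in (0, 1)")
  abs(log(qa / qb)) / e_D
}
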