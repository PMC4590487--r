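#' Fit a random-intercept linear mixed model
#'
#' REML fit of a Gaussian mixed model with a single random intercept, the
#' workhorse of the plumage-similarity and nest-defence analyses. Fitting
#' is delegated to [nlme::lme()]; the returned object standardizes the
#' coefficient table (estimate, s.e., t, p), the marginal term-level tests
#' used by backward elimination, and the random-effect standard deviation.
#' When the between-group variance collapses to (near) zero the fit is
#' flagged with a warning: it is then equivalent to ordinary least
#' squares.
#'
#' @param data Data frame in long format.
#' @param response Response column name.
#' @param fixed_terms Character vector of fixed-effect terms.
#' @param random_intercept_group Grouping column for the random intercept.
#' @param method `"REML"` (default) or `"ML"`.
#' @return Object of class `"mimic_fit"`.
#' @export
fit_lmm <- function(data, response, fixed_terms, random_intercept_group,
                    method = c("REML", "ML")) {
  method <- match.arg(method)
  if (length(unique(data[[random_intercept_group]])) < 2)
    stop("need at least 2 groups for a random intercept")
  fixed <- stats::as.formula(paste(
    response, "~", paste(if (length(fixed_terms)) fixed_terms else "1",
                         collapse = " + ")))
  if (stats::sd(data[[response]]) == 0) {
    # constant response: no model can be estimated; report the boundary fit
    # (all contrasts zero, no evidence against any term)
    warning("response '", response, "' is constant; degenerate boundary fit")
    X <- stats::model.matrix(fixed, data)
    cf <- data.frame(term = colnames(X),
                     estimate = c(data[[response]][1],
                                  rep(0, ncol(X) - 1)),
                     se = 0, df = NA_real_, statistic = NaN,
                     p = c(NaN, rep(1, ncol(X) - 1)),
                     row.names = NULL, stringsAsFactors = FALSE)
    return(structure(list(kind = "lmm", model = NULL, coefficients = cf,
                          term_p = stats::setNames(rep(1, length(fixed_terms)),
                                                   fixed_terms),
                          random_effect_sd = 0, residual_sd = 0,
                          reference = fit_reference_levels(data, fixed_terms),
                          response = response, fixed_terms = fixed_terms,
                          random_group = random_intercept_group),
                     class = "mimic_fit"))
  }
  random <- stats::as.formula(paste("~ 1 |", random_intercept_group))
  fit <- tryCatch(
    nlme::lme(fixed, random = random, data = data, method = method),
    error = function(e) {
      if (grepl("computationally singular|rank|contrasts|Singularity|backsolve",
                conditionMessage(e)))
        stop("singular fixed-effect design for terms: ",
             paste(fixed_terms, collapse = ", "), call. = FALSE)
      stop(e)
    })
  tt <- summary(fit)$tTable
  coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                      se = tt[, "Std.Error"], df = tt[, "DF"],
                      statistic = tt[, "t-value"], p = tt[, "p-value"],
                      row.names = NULL, stringsAsFactors = FALSE)
  an <- stats::anova(fit, type = "marginal")
  term_p <- stats::setNames(an[["p-value"]], rownames(an))
  term_p <- term_p[names(term_p) != "(Intercept)"]
  re_sd <- as.numeric(nlme::VarCorr(fit)["(Intercept)", "StdDev"])
  res_sd <- fit$sigma
  if (re_sd < 1e-6 * res_sd)
    warning("random-intercept variance is at the boundary (~0); ",
            "the fit is equivalent to OLS")
  refs <- fit_reference_levels(data, fixed_terms)
  structure(list(kind = "lmm", model = fit, coefficients = coefs,
                 term_p = term_p, random_effect_sd = re_sd,
                 residual_sd = res_sd, reference = refs,
                 response = response, fixed_terms = fixed_terms,
                 random_group = random_intercept_group),
            class = "mimic_fit")
}

fit_reference_levels <- function(data, terms) {
  refs <- list()
  for (tm in terms) {
    if (!tm %in% names(data)) next
    v <- data[[tm]]
    if (is.factor(v)) refs[[tm]] <- levels(v)[1]
    else if (is.character(v)) refs[[tm]] <- sort(unique(v))[1]
  }
  refs
}

#' Fit a logistic regression
#'
#' Maximum-likelihood logit fit (iteratively reweighted least squares via
#' [stats::glm()]) with Wald Z tests per coefficient and likelihood-ratio
#' tests per term for elimination. Complete or quasi-complete separation
#' is detected from fitted probabilities pinned at 0/1 and reported with
#' the coefficient that diverged.
#'
#' @param data Data frame.
#' @param response Binary response column (0/1, logical, or a factor whose
#'   second level is the event).
#' @param terms Character vector of model terms.
#' @return Object of class `"mimic_fit"`.
#' @export
fit_logistic <- function(data, response, terms) {
  y <- data[[response]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.character(y)) y <- as.integer(factor(y)) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary")
  if (length(unique(y)) < 2)
    warning("degenerate fit: response is constant; intercept-only estimate ",
            "is on the boundary")
  dd <- data
  dd[[response]] <- y
  if (nrow(dd) <= length(terms) + 1)
    stop("more model terms than observations")
  form <- stats::as.formula(paste(
    response, "~", paste(if (length(terms)) terms else "1", collapse = " + ")))
  fit <- suppressWarnings(stats::glm(form, data = dd, family = stats::binomial()))
  if (length(unique(y)) == 2 &&
      (any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8))) {
    cf <- stats::coef(fit)
    worst <- names(cf)[which.max(abs(cf[-1])) + 1L]
    warning(sprintf(
      "possible complete separation: fitted probabilities at 0/1; term '%s' diverging",
      worst))
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], statistic = sm[, "z value"],
                      p = sm[, "Pr(>|z|)"], row.names = NULL,
                      stringsAsFactors = FALSE)
  term_p <- numeric(0)
  if (length(terms)) {
    d1 <- suppressWarnings(stats::drop1(fit, test = "LRT"))
    term_p <- stats::setNames(d1[["Pr(>Chi)"]], rownames(d1))
    term_p <- term_p[!is.na(term_p)]
  }
  structure(list(kind = "logistic", model = fit, coefficients = coefs,
                 term_p = term_p, reference = fit_reference_levels(dd, terms),
                 response = response, fixed_terms = terms),
            class = "mimic_fit")
}

#' @export
print.mimic_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s ~ %s\n", x$kind, x$response,
              paste(x$fixed_terms, collapse = " + ")))
  if (!is.null(x$random_group))
    cat(sprintf("  random intercept: %s (sd = %.4g), residual sd = %.4g\n",
                x$random_group, x$random_effect_sd, x$residual_sd))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Backward elimination of non-significant terms
#'
#' Iteratively refits the model, dropping at each step the removable term
#' with the largest term-level p-value above `alpha`, until every
#' remaining removable term is significant or only protected terms
#' remain. The focal treatment term is protected so the final model
#' always reports its effect. Both the full and the final fits are
#' returned together with the elimination trace.
#'
#' @param fitter Function `(data, terms) -> "mimic_fit"`; see
#'   [lmm_fitter()] and [logistic_fitter()].
#' @param data Data frame.
#' @param full_terms All candidate terms.
#' @param protected Terms never dropped (the focal treatment), default
#'   none.
#' @param alpha Retention threshold, default 0.05.
#' @return List with `full`, `final` (both `"mimic_fit"`) and `trace`
#'   (data frame of dropped terms and their p-values).
#' @export
backward_eliminate <- function(fitter, data, full_terms, protected = character(),
                               alpha = 0.05) {
  full <- fitter(data, full_terms)
  terms <- full_terms
  fit <- full
  trace <- data.frame(step = integer(), dropped = character(), p = numeric(),
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    removable <- setdiff(names(fit$term_p), protected)
    removable <- removable[removable %in% terms]
    if (!length(removable)) break
    p <- fit$term_p[removable]
    if (all(p <= alpha, na.rm = TRUE)) break
    worst <- removable[which.max(p)]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = worst,
                                     p = unname(p[which.max(p)])))
    terms <- setdiff(terms, worst)
    fit <- fitter(data, terms)
  }
  list(full = full, final = fit, trace = trace)
}

#' Convenience fitter factories for [backward_eliminate()]
#'
#' @param response Response column name.
#' @param random_intercept_group Grouping column (LMM only).
#' @return A function `(data, terms) -> "mimic_fit"`.
#' @export
lmm_fitter <- function(response, random_intercept_group) {
  function(data, terms) fit_lmm(data, response, terms, random_intercept_group)
}

#' @rdname lmm_fitter
#' @export
logistic_fitter <- function(response) {
  function(data, terms) fit_logistic(data, response, terms)
}

#' All pairwise contrasts of a categorical term by reference rotation
#'
#' Refits the model with each level of the factor as the reference
#' category and collects the k(k-1)/2 unique pairwise contrasts with
#' their standard errors, test statistics and p-values — the standard way
#' of reading every pairwise comparison out of a single treatment-coded
#' model. Reparameterization leaves fitted values unchanged, so the
#' contrasts are mutually consistent (antisymmetric and additive).
#'
#' @param fitter Function `(data, terms) -> "mimic_fit"`.
#' @param data Data frame.
#' @param terms Model terms, including `categorical_term`.
#' @param categorical_term The factor whose levels are compared.
#' @return Data frame: `level_a, level_b, estimate, se, statistic, p`
#'   where `estimate` is (level_b minus level_a).
#' @export
rotate_reference <- function(fitter, data, terms, categorical_term) {
  v <- data[[categorical_term]]
  if (!is.factor(v)) v <- factor(v)
  lv <- levels(droplevels(v))
  if (length(lv) < 2) stop("categorical term needs at least 2 levels")
  rows <- list()
  for (ref in lv[-length(lv)]) {
    dd <- data
    dd[[categorical_term]] <- stats::relevel(factor(v, levels = lv), ref = ref)
    fit <- fitter(dd, terms)
    cf <- fit$coefficients
    later <- lv[seq(which(lv == ref) + 1L, length(lv))]
    for (other in later) {
      nm <- paste0(categorical_term, other)
      row <- cf[cf$term == nm, , drop = FALSE]
      if (nrow(row) != 1)
        stop(sprintf("contrast coefficient '%s' not found", nm))
      rows[[length(rows) + 1L]] <- data.frame(
        level_a = ref, level_b = other, estimate = row$estimate,
        se = row$se, statistic = row$statistic, p = row$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the three study analyses
#'
#' The full inference stage: (1) plumage similarity — mixed models of the
#' colour JND, luminance JND and log pattern difference of each specimen
#' pair, with taxon group fixed and body region as the random intercept;
#' (2) nest defence — mixed models of alarm calls and mobbing seconds on
#' model type (order, replicate and nest stage in the full model), pair as
#' the random intercept; (3) egg rejection — logistic regression of
#' rejection on model type plus the standardized egg-difference
#' covariates. Each analysis applies backward elimination (protecting the
#' focal treatment) and reference-category rotation for all pairwise
#' treatment contrasts.
#'
#' @param plumage_table Comparison table from [build_comparison_table()]
#'   (or `NULL` to skip).
#' @param trial_table Aggression trials (`pair_id, model_type,
#'   presentation_order, model_replicate, nest_stage, alarm_calls,
#'   mobbing_seconds`), or `NULL`.
#' @param rejection_table Rejection records (`pair_id, model_type,
#'   colour_jnd, luminance_jnd, pattern_diff, shape_diff, volume_diff,
#'   outcome`), or `NULL`.
#' @param alpha Elimination threshold, default 0.05.
#' @return Nested list of `full`/`final` fits, elimination traces and
#'   pairwise contrast tables per analysis.
#' @export
run_study_models <- function(plumage_table = NULL, trial_table = NULL,
                             rejection_table = NULL, alpha = 0.05) {
  out <- list()

  if (!is.null(plumage_table)) {
    need <- c("taxon_group", "region", "colour_jnd", "luminance_jnd", "log_s_diff")
    miss <- setdiff(need, names(plumage_table))
    if (length(miss)) stop("plumage table lacks columns: ",
                           paste(miss, collapse = ", "))
    plumage_table$taxon_group <- factor(plumage_table$taxon_group)
    out$plumage <- lapply(
      stats::setNames(c("colour_jnd", "luminance_jnd", "log_s_diff"),
                      c("colour", "luminance", "pattern")),
      function(resp) {
        fitter <- lmm_fitter(resp, "region")
        el <- backward_eliminate(fitter, plumage_table, "taxon_group",
                                 protected = "taxon_group", alpha = alpha)
        el$contrasts <- rotate_reference(fitter, plumage_table,
                                         el$final$fixed_terms, "taxon_group")
        el
      })
  }

  if (!is.null(trial_table)) {
    need <- c("pair_id", "model_type", "presentation_order", "model_replicate",
              "nest_stage", "alarm_calls", "mobbing_seconds")
    miss <- setdiff(need, names(trial_table))
    if (length(miss)) stop("trial table lacks columns: ",
                           paste(miss, collapse = ", "))
    trial_table$model_type <- factor(trial_table$model_type)
    trial_table$model_replicate <- factor(trial_table$model_replicate)
    trial_table$nest_stage <- factor(trial_table$nest_stage)
    full_terms <- c("model_type", "presentation_order", "model_replicate",
                    "nest_stage")
    out$aggression <- lapply(
      stats::setNames(c("alarm_calls", "mobbing_seconds"),
                      c("alarm_calls", "mobbing")),
      function(resp) {
        fitter <- lmm_fitter(resp, "pair_id")
        el <- backward_eliminate(fitter, trial_table, full_terms,
                                 protected = "model_type", alpha = alpha)
        el$contrasts <- rotate_reference(fitter, trial_table,
                                         el$final$fixed_terms, "model_type")
        el
      })
  }

  if (!is.null(rejection_table)) {
    need <- c("pair_id", "model_type", "colour_jnd", "luminance_jnd",
              "pattern_diff", "shape_diff", "volume_diff", "outcome")
    miss <- setdiff(need, names(rejection_table))
    if (length(miss)) stop("rejection table lacks columns: ",
                           paste(miss, collapse = ", "))
    rt <- rejection_table
    rt$model_type <- factor(rt$model_type)
    covars <- c("colour_jnd", "luminance_jnd", "pattern_diff", "shape_diff",
                "volume_diff")
    for (cv in covars) {
      s <- stats::sd(rt[[cv]])
      if (is.finite(s) && s > 0) rt[[cv]] <- as.numeric(scale(rt[[cv]]))
    }
    fitter <- logistic_fitter("outcome")
    el <- backward_eliminate(fitter, rt, c("model_type", covars),
                             protected = "model_type", alpha = alpha)
    el$contrasts <- rotate_reference(fitter, rt, el$final$fixed_terms,
                                     "model_type")
    out$rejection <- el
  }
  out
}
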