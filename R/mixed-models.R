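# Crossed random-intercept mixed-effects models, fitted by maximum
# likelihood (so fixed-effect ladders are comparable by likelihood-ratio
# test), with AIC, Wald coefficient tests, variance components and
# marginal/conditional R-squared from the variance-component decomposition.

#' Specify a mixed model
#'
#' @param outcome Outcome column name.
#' @param fixed Character vector of fixed-effect terms (factors, covariates,
#'   interactions such as `"weather:season"`); empty means intercept-only.
#' @param random Character vector of grouping columns, each receiving a
#'   random intercept; crossed, not nested (default participant and image).
#' @param family `"gaussian"` (identity link, the default) or `"gamma-log"`
#'   (Gamma with log link, for strictly positive skewed outcomes).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(outcome, fixed = character(),
                       random = c("participant_id", "image_id"),
                       family = c("gaussian", "gamma-log")) {
  family <- match.arg(family)
  if (length(random) < 1) stop("at least one random intercept is required",
                               call. = FALSE)
  structure(list(outcome = outcome, fixed = as.character(fixed),
                 random = random, family = family),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  as.formula(paste0(spec$outcome, " ~ ", rhs, " + ",
                    paste(sprintf("(1 | %s)", spec$random), collapse = " + ")))
}

# Expanded fixed-term labels (interactions expanded, e.g. a*b -> a, b, a:b).
expanded_terms <- function(fixed) {
  if (length(fixed) == 0) return(character())
  attr(terms(reformulate(fixed)), "term.labels")
}

# Re-level known design factors onto their canonical reference order so
# contrasts read Urban / Low / blue / spring_summer as reference levels.
canonical_factors <- function(data) {
  canon <- list(environment = ENV_LEVELS, horizon = HORIZON_LEVELS,
                vantage = VANTAGE_LEVELS, weather = WEATHER_LEVELS,
                season = SEASON_LEVELS)
  for (nm in intersect(names(canon), names(data))) {
    vals <- unique(as.character(data[[nm]]))
    if (all(vals %in% canon[[nm]]))
      data[[nm]] <- factor(data[[nm]],
                           levels = intersect(canon[[nm]], vals))
  }
  data
}

#' Fit a crossed random-intercept mixed model
#'
#' Fits the specified model by maximum likelihood with `lme4` (Gaussian:
#' `lmer(REML = FALSE)`; gamma-log: `glmer`).  Coefficient p-values are
#' Wald z tests (normal approximation).  Non-convergence is reported in the
#' fit object, not raised as an error; a rank-deficient fixed design is an
#' error naming the aliased terms.
#'
#' @param spec A [model_spec()].
#' @param data Data frame containing the outcome, all fixed terms and the
#'   random-effect grouping columns (each with >= 2 levels).
#' @return Object of class `sky_model_fit` with elements `coefficients`
#'   (term, estimate, se, z, p), `varcomp` (`random` named vector and
#'   `residual`), `logLik`, `npar`, `aic`, `n`, `var_fixed`,
#'   `marginal_r2`/`conditional_r2` (Gaussian fits), `converged`,
#'   `messages`, and the underlying lme4 `fit`.
#' @export
fit_mixed_model <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c(spec$outcome, spec$random,
            unique(unlist(strsplit(spec$fixed, "[:*]"))))
  miss <- setdiff(trimws(need), c(names(data), ""))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (rc in spec$random) {
    if (length(unique(data[[rc]])) < 2)
      stop(sprintf("random factor '%s' needs >= 2 levels", rc), call. = FALSE)
  }
  data <- canonical_factors(data)
  fixed_formula <- if (length(spec$fixed)) reformulate(spec$fixed) else ~1
  X <- model.matrix(fixed_formula, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  form <- spec_formula(spec)
  msgs <- character()
  fit <- withCallingHandlers({
    if (spec$family == "gaussian")
      lme4::lmer(form, data = data, REML = FALSE)
    else
      lme4::glmer(form, data = data, family = stats::Gamma(link = "log"))
  },
  warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
  },
  message = function(m) {
    msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
  })
  msgs <- c(msgs, unlist(fit@optinfo$conv$lme4$messages))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- beta / se
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), z = unname(z),
                      p = unname(2 * pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)
  random_var <- vapply(spec$random, function(g) {
    if (g %in% names(vc)) vc[[g]][1, 1] else NA_real_
  }, numeric(1))
  resid_var <- sigma(fit)^2
  ll <- stats::logLik(fit)
  npar <- attr(ll, "df")
  Xf <- lme4::getME(fit, "X")
  var_fixed <- var(as.vector(Xf %*% beta))
  degenerate <- spec$family == "gaussian" && resid_var < 1e-10
  out <- structure(list(
    spec = spec, formula = form, fit = fit, coefficients = coefs,
    varcomp = list(random = random_var, residual = resid_var),
    logLik = as.numeric(ll), npar = npar,
    aic = 2 * npar - 2 * as.numeric(ll),
    n = stats::nobs(fit), var_fixed = var_fixed,
    converged = length(msgs) == 0 && !degenerate,
    degenerate = degenerate, messages = msgs),
    class = "sky_model_fit")
  if (spec$family == "gaussian") {
    tot <- var_fixed + sum(random_var) + resid_var
    if (tot > 0) {
      out$marginal_r2 <- var_fixed / tot
      out$conditional_r2 <- (var_fixed + sum(random_var)) / tot
    }
  }
  out
}

#' @export
print.sky_model_fit <- function(x, ...) {
  cat("Mixed model (", x$spec$family, ", ML): ",
      deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.1f\n", x$n, x$logLik, x$aic))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat("  variance components: ",
      paste(sprintf("%s %.3f", names(x$varcomp$random), x$varcomp$random),
            collapse = ", "),
      sprintf(", residual %.3f\n", x$varcomp$residual))
  if (!is.null(x$marginal_r2))
    cat(sprintf("  marginal R2 = %.3f, conditional R2 = %.3f\n",
                x$marginal_r2, x$conditional_r2))
  if (!x$converged)
    cat("  [flagged:", paste(unique(x$messages), collapse = "; "),
        if (isTRUE(x$degenerate)) "degenerate residual variance", "]\n")
  invisible(x)
}

#' Marginal and conditional R-squared from variance components
#'
#' The variance-component decomposition for Gaussian mixed models:
#' marginal R2 is the fixed-effect share
#' `var_f / (var_f + sum(var_random) + var_resid)` where `var_f` is the
#' variance of the fixed-effect linear predictor over the data; conditional
#' R2 adds the random-intercept components to the numerator.
#'
#' @param fit A Gaussian [fit_mixed_model()] result.
#' @return Named list `marginal_r2`, `conditional_r2`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "sky_model_fit"))
  if (fit$spec$family != "gaussian")
    stop("variance-component R2 implemented for Gaussian fits only",
         call. = FALSE)
  r2_components(fit$var_fixed, fit$varcomp$random, fit$varcomp$residual)
}

#' @rdname r2_nakagawa
#' @param var_fixed Variance of the fixed-effect linear predictor.
#' @param var_random Named vector of random-intercept variances.
#' @param var_residual Residual variance.
#' @export
r2_components <- function(var_fixed, var_random, var_residual) {
  tot <- var_fixed + sum(var_random) + var_residual
  if (tot <= 0) stop("zero total variance: R2 undefined", call. = FALSE)
  list(marginal_r2 = var_fixed / tot,
       conditional_r2 = (var_fixed + sum(var_random)) / tot)
}

#' Likelihood-ratio test between nested mixed models
#'
#' Both fits must be maximum-likelihood fits of the same outcome on the
#' same rows, with the reduced model's fixed terms a subset of the full
#' model's.  The statistic is `2 (logLik_full - logLik_reduced)` with df
#' equal to the parameter-count difference.
#'
#' @param fit_reduced,fit_full [fit_mixed_model()] results.
#' @return A test-result object (chi-square statistic, df, p).
#' @export
lrt <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "sky_model_fit"),
            inherits(fit_full, "sky_model_fit"))
  if (fit_reduced$n != fit_full$n)
    stop("models were fitted to different numbers of rows", call. = FALSE)
  if (!identical(fit_reduced$spec$outcome, fit_full$spec$outcome))
    stop("models have different outcomes", call. = FALSE)
  tr <- expanded_terms(fit_reduced$spec$fixed)
  tf <- expanded_terms(fit_full$spec$fixed)
  if (!all(tr %in% tf))
    stop("models are not nested: reduced terms ",
         paste(setdiff(tr, tf), collapse = ", "),
         " are absent from the full model", call. = FALSE)
  stat <- max(0, 2 * (fit_full$logLik - fit_reduced$logLik))
  df <- fit_full$npar - fit_reduced$npar
  p <- if (df == 0) as.numeric(stat <= 1e-8) else
    pchisq(stat, df, lower.tail = FALSE)
  test_result("Likelihood ratio", stat, df, p)
}

#' Run a stepwise mixed-model ladder
#'
#' Fits an ordered sequence of model specifications, each optionally on a
#' row subset, and compares each step to its stated predecessor by AIC and
#' likelihood-ratio test.  Steps whose subset leaves fewer than `min_rows`
#' rows are skipped with a diagnostic.  The AIC-preferred step is reported
#' within each group of steps sharing an outcome and row set (AIC is not
#' comparable across different data).
#'
#' @param data Analysis-ready data frame.
#' @param ladder List of steps; each step is a list with `name`, `outcome`,
#'   `fixed` (character vector of terms), optional `subset` (a function of
#'   the data frame returning a logical row mask), optional `compare_to`
#'   (the name of an earlier step) and optional `family`.
#' @param random Random-intercept columns for every step.
#' @param min_rows Minimum rows a step needs to be fitted (default 20).
#' @return Object of class `model_ladder`: per-step results (`fit`,
#'   `comparison`, `n_rows`, `n_images`) plus a `summary` data frame with
#'   AIC, R2 and LRT columns and the preferred flag.
#' @export
run_model_ladder <- function(data, ladder,
                             random = c("participant_id", "image_id"),
                             min_rows = 20) {
  steps <- vector("list", length(ladder))
  names(steps) <- vapply(ladder, function(s) s$name, "")
  for (i in seq_along(ladder)) {
    st <- ladder[[i]]
    rows <- if (is.null(st$subset)) rep(TRUE, nrow(data)) else st$subset(data)
    d <- data[rows, , drop = FALSE]
    rec <- list(name = st$name, fixed = st$fixed, n_rows = nrow(d),
                n_images = if (length(random) > 1 && random[2] %in% names(d))
                  length(unique(d[[random[2]]])) else NA_integer_,
                skipped = FALSE, comparison = NULL)
    if (nrow(d) < min_rows) {
      rec$skipped <- TRUE
      rec$diagnostic <- sprintf("subset leaves %d < %d rows", nrow(d),
                                min_rows)
      steps[[i]] <- rec
      next
    }
    spec <- model_spec(st$outcome, st$fixed, random = random,
                       family = st$family %||% "gaussian")
    rec$fit <- fit_mixed_model(spec, d)
    if (!is.null(st$compare_to) && !is.null(steps[[st$compare_to]]$fit)) {
      prev <- steps[[st$compare_to]]$fit
      if (prev$n == rec$fit$n) {
        rec$comparison <- list(
          against = st$compare_to,
          delta_aic = rec$fit$aic - prev$aic,
          lrt = tryCatch(lrt(prev, rec$fit), error = function(e) NULL))
      } else {
        rec$diagnostic <- sprintf(
          "not compared to '%s': different row sets (%d vs %d)",
          st$compare_to, prev$n, rec$fit$n)
      }
    }
    steps[[i]] <- rec
  }
  summ <- do.call(rbind, lapply(steps, function(s) {
    data.frame(
      step = s$name, n = s$n_rows, n_images = s$n_images,
      skipped = s$skipped,
      aic = if (!is.null(s$fit)) s$fit$aic else NA_real_,
      marginal_r2 = if (!is.null(s$fit)) s$fit$marginal_r2 %||% NA_real_
        else NA_real_,
      conditional_r2 = if (!is.null(s$fit)) s$fit$conditional_r2 %||% NA_real_
        else NA_real_,
      lrt_stat = if (!is.null(s$comparison$lrt)) s$comparison$lrt$statistic
        else NA_real_,
      lrt_df = if (!is.null(s$comparison$lrt)) s$comparison$lrt$df
        else NA_real_,
      lrt_p = if (!is.null(s$comparison$lrt)) s$comparison$lrt$p_value
        else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  summ$preferred <- FALSE
  fitted <- !summ$skipped & !is.na(summ$aic)
  for (nr in unique(summ$n[fitted])) {
    grp <- which(fitted & summ$n == nr)
    summ$preferred[grp[which.min(summ$aic[grp])]] <- TRUE
  }
  structure(list(steps = steps, summary = summ), class = "model_ladder")
}

#' @export
print.model_ladder <- function(x, ...) {
  cat("<model_ladder>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Default ladder for the sky selection score
#'
#' The stepwise sequence used for the sky EDB outcome: environment alone;
#' environment + horizon; horizon alone; horizon + weather; their
#' interaction; horizon + weather + season; and horizon + weather x season.
#' Each step names the predecessor it is compared to.
#'
#' @param outcome Outcome column (default `"edb_sky"`).
#' @return A ladder list for [run_model_ladder()].
#' @export
default_sky_ladder <- function(outcome = "edb_sky") {
  list(
    list(name = "environment", outcome = outcome, fixed = "environment"),
    list(name = "environment+horizon", outcome = outcome,
         fixed = c("environment", "horizon"), compare_to = "environment"),
    list(name = "horizon", outcome = outcome, fixed = "horizon"),
    list(name = "horizon+weather", outcome = outcome,
         fixed = c("horizon", "weather"), compare_to = "horizon"),
    list(name = "horizon*weather", outcome = outcome,
         fixed = c("horizon", "weather", "horizon:weather"),
         compare_to = "horizon+weather"),
    list(name = "horizon+weather+season", outcome = outcome,
         fixed = c("horizon", "weather", "season"),
         compare_to = "horizon+weather"),
    list(name = "horizon+weather*season", outcome = outcome,
         fixed = c("horizon", "weather", "season", "weather:season"),
         compare_to = "horizon+weather"))
}

#' Default ladder for naturalness ratings
#'
#' Naturalness modelled from the subjective selection scores on the subset
#' of presentations where both trees and sky were present and selected-able
#' (sky and trees scores > 0 screens out structural zeros): sky selection,
#' tree selection, and their sum.
#'
#' @param outcome Outcome column (default `"naturalness"`).
#' @return A ladder list for [run_model_ladder()].
#' @export
default_naturalness_ladder <- function(outcome = "naturalness") {
  both <- function(d) d$edb_sky > 0 & d$edb_trees > 0
  list(
    list(name = "edb_sky", outcome = outcome, fixed = "edb_sky",
         subset = both),
    list(name = "edb_trees", outcome = outcome, fixed = "edb_trees",
         subset = both),
    list(name = "edb_sky+edb_trees", outcome = outcome,
         fixed = c("edb_sky", "edb_trees"), subset = both,
         compare_to = "edb_sky"))
}
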