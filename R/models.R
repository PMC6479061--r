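# Cross-sectional and longitudinal models of per-sample repertoire summaries.

new_model_result <- function(terms, contrasts, formula, n, converged,
                             type, note = NULL, fit = NULL) {
  structure(list(terms = terms, contrasts = contrasts, formula = formula,
                 n = n, converged = converged, type = type, note = note,
                 fit = fit),
            class = "bcrdyn_model")
}

#' @export
print.bcrdyn_model <- function(x, ...) {
  cat(x$type, "model:", x$formula, "\n")
  cat("n =", x$n, if (!x$converged) "(did not fully converge)", "\n")
  print(format(x$terms, digits = 4), row.names = FALSE)
  if (!is.null(x$contrasts) && nrow(x$contrasts)) {
    cat("contrasts:\n")
    print(format(x$contrasts, digits = 4), row.names = FALSE)
  }
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.bcrdyn_model <- function(object, ...) {
  stats::setNames(object$terms$estimate, object$terms$term)
}

# All pairwise differences between outcome-group levels from a fitted lm:
# estimate, SE via the coefficient covariance, two-sided t p-value.
pairwise_group_contrasts <- function(fit, levels_present) {
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  coef_of <- function(g) {
    if (g == levels_present[1]) return(NULL)
    paste0("outcome", g)
  }
  pairs <- utils::combn(levels_present, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    k <- stats::setNames(rep(0, length(cf)), names(cf))
    a <- coef_of(p[2]); b <- coef_of(p[1])
    if (!is.null(a)) k[a] <- 1
    if (!is.null(b)) k[b] <- -1
    est <- sum(k * cf)
    se <- sqrt(drop(t(k) %*% V %*% k))
    tval <- est / se
    data.frame(contrast = paste(p[2], "-", p[1]), estimate = est,
               std_error = se, statistic = tval,
               p_value = 2 * stats::pt(-abs(tval), df = fit$df.residual),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-sectional linear model of a repertoire summary
#'
#' Ordinary least squares of a per-sample response (richness, entropy, SHM,
#' Gini index or gene usage) on clinical outcome group at one time point,
#' optionally adjusted for clinical covariates.  NP is the reference group;
#' all pairwise group contrasts are reported (unadjusted).
#'
#' @param records Per-sample `data.frame` holding the response column and
#'   `sample_id`.
#' @param meta Sample metadata (`sample_id`, `subject_id`, `time_months`,
#'   `outcome`, covariates).
#' @param response Name of the response column in `records`.
#' @param time Time point (months) to subset to; `NULL` uses all rows.
#' @param covariates Character vector of covariate column names in `meta`.
#' @return A `bcrdyn_model` object: per-term estimates/SE/p-values plus
#'   pairwise group contrasts.
#' @export
fit_cross_sectional <- function(records, meta, response, time = NULL,
                                covariates = NULL) {
  dat <- merge(records, meta, by = "sample_id",
               suffixes = c("", ".meta"))
  if (!is.null(time)) dat <- dat[dat$time_months == time, , drop = FALSE]
  dat$outcome <- outcome_factor(dat$outcome)
  if (nlevels(dat$outcome) < 2) {
    stop("need at least two outcome groups at this time point")
  }
  rhs <- paste(c("outcome", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; aliased term(s): ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      std_error = sm[, 2], statistic = sm[, 3],
                      p_value = sm[, 4], stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  contrasts <- pairwise_group_contrasts(fit, levels(dat$outcome))
  new_model_result(terms, contrasts, deparse(fml), nrow(dat), TRUE,
                   "cross-sectional OLS", fit = fit)
}

#' Conditional-growth linear mixed model of longitudinal diversity
#'
#' Fixed effects: outcome group, time in months and their interaction (plus
#' optional covariates); random effects: per-subject intercept and time
#' slope, fitted by REML.  The group-by-time interaction is the headline
#' test: its joint Satterthwaite F-test p-value is reported alongside the
#' per-term table.  On a singular random-slope fit the model falls back to
#' a random intercept only; if mixed-model fitting fails altogether (e.g. a
#' response with no residual variation) a fixed-effects-only fallback is
#' used and the convergence flag is lowered — no exception is thrown.
#'
#' @param records Per-sample `data.frame` with the response column.
#' @param meta Sample metadata with `subject_id` and `time_months`.
#' @param response Response column name.
#' @param covariates Covariate column names in `meta`.
#' @param random_slope Start from a per-subject random time slope
#'   (default) or intercept-only.
#' @return A `bcrdyn_model`; `$interaction` holds the joint interaction
#'   test (F statistic, degrees of freedom, p-value).
#' @export
fit_growth_lmm <- function(records, meta, response, covariates = NULL,
                           random_slope = TRUE) {
  dat <- merge(records, meta, by = "sample_id", suffixes = c("", ".meta"))
  dat$outcome <- outcome_factor(dat$outcome)
  rhs <- paste(c("outcome * time_months", covariates), collapse = " + ")
  note <- NULL
  converged <- TRUE
  fit <- NULL
  forms <- c(
    if (random_slope)
      paste(response, "~", rhs, "+ (1 + time_months | subject_id)"),
    paste(response, "~", rhs, "+ (1 | subject_id)")
  )
  for (f in forms) {
    fit_try <- tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(stats::as.formula(f), data = dat, REML = TRUE,
                       control = lme4::lmerControl(calc.derivs = FALSE))
      )),
      error = function(e) NULL
    )
    if (!is.null(fit_try) && !lme4::isSingular(fit_try, tol = 1e-4)) {
      fit <- fit_try
      if (f != forms[1]) note <- "random slope singular; intercept-only fit"
      break
    }
    if (!is.null(fit_try) && is.null(fit)) {
      fit <- fit_try  # keep singular fit as last resort
      note <- "singular random-effects fit"
    }
  }
  if (!is.null(fit) && inherits(fit, "lmerModLmerTest")) {
    sm <- stats::coef(summary(fit))
    terms <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        std_error = sm[, "Std. Error"], df = sm[, "df"],
                        statistic = sm[, "t value"],
                        p_value = sm[, "Pr(>|t|)"], stringsAsFactors = FALSE)
    av <- tryCatch(stats::anova(fit, type = 3), error = function(e) NULL)
    interaction <- NULL
    if (!is.null(av) && "outcome:time_months" %in% rownames(av)) {
      r <- av["outcome:time_months", ]
      interaction <- data.frame(term = "outcome:time_months",
                                f_value = r[["F value"]],
                                df1 = r[["NumDF"]], df2 = r[["DenDF"]],
                                p_value = r[["Pr(>F)"]],
                                stringsAsFactors = FALSE)
    }
    fml <- paste(deparse(stats::formula(fit)), collapse = " ")
  } else {
    # fixed-effects fallback: zero-variance or otherwise unfittable data
    converged <- FALSE
    note <- paste(c(note, "mixed model unfittable; OLS fallback"),
                  collapse = "; ")
    fml <- paste(response, "~", rhs)
    fit <- stats::lm(stats::as.formula(fml), data = dat)
    sm <- summary(fit)$coefficients
    terms <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        std_error = sm[, 2], df = fit$df.residual,
                        statistic = sm[, 3], p_value = sm[, 4],
                        stringsAsFactors = FALSE)
    interaction <- NULL
  }
  rownames(terms) <- NULL
  res <- new_model_result(terms, NULL, fml, nrow(dat), converged,
                          "conditional-growth LMM", note = note, fit = fit)
  res$interaction <- interaction
  res
}
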