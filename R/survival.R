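# Survival-model selection pipeline: censoring, stratified splitting,
# univariable Cox screening, all-subset model enumeration with an
# all-covariates-significant filter, 5-fold cross-validated ranking by
# Harrell's C-index, Kaplan-Meier stratification, and the 3-point
# recurrence risk score. Cox fits use survival::coxph with the Efron tie
# approximation; Harrell's C is computed by this package with the
# convention that only pairs whose shorter time is an event (and times are
# strictly unequal) are comparable, and tied risks count one half.

#' Censor recurrence-free survival at a follow-up horizon
#'
#' Records with follow-up beyond `horizon_months` are administratively
#' censored: the time is truncated to the horizon and the event indicator
#' cleared.
#'
#' @param cohort data frame with columns `rfs_months` (positive) and `event`
#'   (0/1).
#' @param horizon_months censoring horizon (default 60, i.e. 5 years);
#'   `Inf` leaves the cohort unchanged.
#' @return The censored cohort.
#' @export
censor_rfs <- function(cohort, horizon_months = 60) {
  if (!is.numeric(horizon_months) || length(horizon_months) != 1L ||
      is.na(horizon_months) || horizon_months <= 0)
    stop("`horizon_months` must be a single positive number", call. = FALSE)
  if (any(cohort$rfs_months <= 0))
    stop("`rfs_months` must be positive", call. = FALSE)
  over <- cohort$rfs_months > horizon_months
  cohort$event[over] <- 0L
  cohort$rfs_months[over] <- horizon_months
  cohort
}

#' Event-stratified train/test split
#'
#' Randomly splits the cohort into a training and a hold-out test set with a
#' similar proportion of events in both (the split is stratified on the
#' event indicator, so the proportions differ by less than one event's
#' worth).
#'
#' @param cohort data frame with an `event` column.
#' @param n_train,n_test set sizes; must sum to `nrow(cohort)` (defaults
#'   117/40).
#' @param seed RNG seed for reproducibility.
#' @return List with elements `train` and `test`.
#' @export
split_cohort <- function(cohort, n_train = 117, n_test = 40, seed = NULL) {
  n <- nrow(cohort)
  if (n_train + n_test != n)
    stop("`n_train` + `n_test` must equal the cohort size (", n, ")",
         call. = FALSE)
  .with_seed(seed, {
    ev <- which(cohort$event == 1)
    ce <- which(cohort$event != 1)
    ne_train <- round(length(ev) * n_train / n)
    ne_train <- min(max(ne_train, n_train - length(ce)), n_train, length(ev))
    train_idx <- c(sample(ev, ne_train), sample(ce, n_train - ne_train))
    list(train = cohort[sort(train_idx), , drop = FALSE],
         test = cohort[sort(setdiff(seq_len(n), train_idx)), , drop = FALSE])
  })
}

# Cox fit on `covariates` (column names) with Efron ties; returns a
# cox_model_result. Non-convergence and separation are flagged, not fatal.
.fit_cox <- function(cohort, covariates, feature_label = NULL) {
  dat <- cohort[stats::complete.cases(cohort[, covariates, drop = FALSE]), ,
                drop = FALSE]
  res <- list(covariates = covariates,
              feature = feature_label %||% paste(covariates, collapse = " + "),
              n = nrow(dat), n_event = sum(dat$event == 1),
              flagged = FALSE, reason = "")
  class(res) <- "cox_model_result"
  degenerate <- vapply(covariates, function(v)
    length(unique(dat[[v]])) < 2L, logical(1))
  if (nrow(dat) == 0L || res$n_event == 0L || any(degenerate)) {
    res$flagged <- TRUE
    res$reason <- if (any(degenerate)) "constant covariate" else "no events"
    return(res)
  }
  f <- stats::as.formula(paste(
    "survival::Surv(rfs_months, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  warn <- character(0)
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(f, data = dat, ties = "efron"),
             error = function(e) e),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    res$flagged <- TRUE
    res$reason <- conditionMessage(fit)
    return(res)
  }
  s <- summary(fit)
  co <- s$coefficients
  res$table <- data.frame(term = rownames(co),
                          coef = co[, "coef"],
                          hr = co[, "exp(coef)"],
                          se = co[, "se(coef)"],
                          p = co[, "Pr(>|z|)"],
                          row.names = NULL)
  res$loglik <- fit$loglik[length(fit$loglik)]
  res$aic <- 2 * length(stats::coef(fit)) - 2 * res$loglik
  lp <- unname(fit$linear.predictors)
  res$train_cindex <- harrell_c(lp, dat$rfs_months, dat$event)
  res$fit <- fit
  if (length(warn) || anyNA(stats::coef(fit))) {
    res$flagged <- TRUE
    res$reason <- if (length(warn)) paste(warn, collapse = "; ") else
      "inestimable coefficient"
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cox_model_result <- function(x, ...) {
  cat("Cox model:", x$feature,
      sprintf("(n = %d, events = %d)\n", x$n, x$n_event))
  if (!is.null(x$table)) {
    print(format(x$table, digits = 4), row.names = FALSE)
    cat(sprintf("logLik = %.3f, AIC = %.3f, train C = %.4f\n",
                x$loglik, x$aic, x$train_cindex))
  }
  if (x$flagged) cat("flagged:", x$reason, "\n")
  invisible(x)
}

#' Univariable Cox screening of one feature
#'
#' Single-covariate proportional-hazards fit (partial likelihood, Efron
#' ties) reporting the hazard ratio, Wald p-value, log-likelihood and AIC.
#' Rows with a missing covariate value are dropped. Non-convergence or
#' complete separation (e.g. a grade category with zero events) yields a
#' flagged result, not an error.
#'
#' @param cohort data frame with `rfs_months`, `event` and the feature
#'   column.
#' @param feature name of the covariate column.
#' @return A `cox_model_result` (list with `table` of term/hr/p, `loglik`,
#'   `aic`, `train_cindex`, `flagged`, `reason`).
#' @export
univariable_cox <- function(cohort, feature) {
  if (!feature %in% names(cohort))
    stop("unknown feature column: ", feature, call. = FALSE)
  .fit_cox(cohort, feature, feature_label = feature)
}

#' Select features significant in univariable screening
#'
#' Keeps the features whose univariable Wald p-value is strictly below
#' `alpha`; flagged (non-converged or separated) fits are never selected.
#'
#' @param results list of `cox_model_result` from [univariable_cox()].
#' @param alpha significance threshold (default 0.05, strict `<`).
#' @return Character vector of selected feature names.
#' @export
select_features <- function(results, alpha = 0.05) {
  if (length(results) == 0L) return(character(0))
  keep <- vapply(results, function(r) {
    !is.null(r$table) && !r$flagged && is.finite(min(r$table$p)) &&
      min(r$table$p) < alpha
  }, logical(1))
  vapply(results[keep], `[[`, character(1), "feature")
}

#' Enumerate all multivariable covariate combinations
#'
#' All subsets of size two or more of the screened features. Combinations
#' that mix collinear or redundant covariates (e.g. both gradient
#' indicators, or overlapping history flags) are enumerated like any other;
#' the all-covariates-significant filter of [fit_and_filter()] is what
#' removes them, as an outcome of fitting rather than a prior exclusion.
#'
#' @param features character vector of covariate names.
#' @return List of character vectors (possibly empty).
#' @export
enumerate_models <- function(features) {
  n <- length(features)
  if (n < 2L) return(list())
  out <- list()
  for (k in 2:n)
    out <- c(out, utils::combn(features, k, simplify = FALSE))
  out
}

#' Fit candidate models and keep those with all covariates significant
#'
#' Each combination is fitted on the training set; a model is retained only
#' if it converged and every covariate's Wald p-value is strictly below
#' `alpha`. AIC, log-likelihood and the training C-index are recorded for
#' every retained model.
#'
#' @param train training cohort.
#' @param combos list of covariate-name vectors, from [enumerate_models()].
#' @param alpha per-covariate significance threshold (default 0.05).
#' @return List of retained `cox_model_result`s.
#' @export
fit_and_filter <- function(train, combos, alpha = 0.05) {
  fits <- lapply(combos, function(cv) .fit_cox(train, cv))
  keep <- vapply(fits, function(r) {
    !r$flagged && !is.null(r$table) && !anyNA(r$table$p) &&
      all(r$table$p < alpha)
  }, logical(1))
  fits[keep]
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted risk ordering
#' matches the observed event ordering. A pair is comparable when the
#' shorter of the two times ends in an event and the times differ; the
#' member with the shorter time should have the higher risk. Tied risks in
#' a comparable pair count one half.
#'
#' @param risks numeric risk scores (higher = expected earlier event).
#' @param times follow-up times.
#' @param events event indicators (0/1).
#' @return Concordance in `[0, 1]`; `NA` with a warning when no pair is
#'   comparable.
#' @export
harrell_c <- function(risks, times, events) {
  n <- length(risks)
  stopifnot(length(times) == n, length(events) == n)
  if (n < 2L) {
    warning("concordance undefined for fewer than 2 subjects")
    return(NA_real_)
  }
  dt <- outer(times, times, "<")                    # dt[i,j]: t_i < t_j
  comparable <- dt & (events == 1)                  # i has the event
  dr <- outer(risks, risks, "-")
  conc <- sum(comparable & dr > 0) + 0.5 * sum(comparable & dr == 0)
  m <- sum(comparable)
  if (m == 0L) {
    warning("no comparable pairs; concordance undefined")
    return(NA_real_)
  }
  conc / m
}

#' Cross-validated Harrell's C for one covariate set
#'
#' Event-stratified k-fold cross-validation on the training set: for each
#' fold the model is refitted on the remaining folds and Harrell's C is
#' computed on the held-out fold using the linear predictor as the risk
#' score; the mean over folds is returned.
#'
#' @param train training cohort.
#' @param covariates character vector of covariate names.
#' @param k number of folds (default 5); every fold must contain at least
#'   two subjects, so `k = n` (single-subject folds carry no comparable
#'   pairs) is an error.
#' @param seed RNG seed for the fold assignment.
#' @return Mean validation C-index, with attribute `fold_cindex`.
#' @export
cross_validate <- function(train, covariates, k = 5, seed = NULL) {
  n <- nrow(train)
  if (!.is_count(k) || k < 2L) stop("`k` must be an integer >= 2", call. = FALSE)
  if (n / k < 2) stop("folds of fewer than 2 subjects carry no comparable pairs",
                      call. = FALSE)
  folds <- .with_seed(seed, .stratified_folds(train$event, k))
  cs <- vapply(seq_len(k), function(f) {
    fit <- .fit_cox(train[folds != f, , drop = FALSE], covariates)
    # a flagged fit (e.g. separation) can still rank subjects, as long as
    # its coefficients are estimable
    if (is.null(fit$fit) || anyNA(stats::coef(fit$fit))) return(NA_real_)
    held <- train[folds == f, , drop = FALSE]
    held <- held[stats::complete.cases(held[, covariates, drop = FALSE]), ,
                 drop = FALSE]
    lp <- unname(stats::predict(fit$fit, newdata = held, type = "lp"))
    suppressWarnings(harrell_c(lp, held$rfs_months, held$event))
  }, numeric(1))
  structure(mean(cs, na.rm = TRUE), fold_cindex = cs)
}

# event-stratified fold labels 1..k
.stratified_folds <- function(event, k) {
  folds <- integer(length(event))
  for (g in unique(event)) {
    idx <- which(event == g)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Kaplan-Meier curves with pairwise log-rank tests
#'
#' Product-limit survival estimates per group and two-sided pairwise
#' log-rank p-values (reported without multiplicity correction).
#'
#' @param cohort data frame with `rfs_months` and `event`.
#' @param groups vector of group labels, one per row.
#' @return A list of class `km_result`: `curves` (data frame `group`,
#'   `time`, `n_risk`, `survival`), `pairwise_p` (symmetric matrix), `fit`
#'   (the `survfit` object).
#' @export
km_logrank <- function(cohort, groups) {
  stopifnot(nrow(cohort) == length(groups))
  dat <- data.frame(rfs_months = cohort$rfs_months, event = cohort$event,
                    group = factor(groups))
  fit <- survival::survfit(survival::Surv(rfs_months, event) ~ group,
                           data = dat)
  lev <- levels(dat$group)
  if (length(lev) > 1L) {
    gname <- rep(lev, fit$strata)
  } else gname <- rep(lev, length(fit$time))
  curves <- data.frame(group = gname, time = fit$time, n_risk = fit$n.risk,
                       survival = fit$surv)
  pw <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  if (length(lev) > 1L) {
    for (i in seq_along(lev)[-length(lev)]) for (j in (i + 1):length(lev)) {
      sub <- dat[dat$group %in% lev[c(i, j)], ]
      sd <- tryCatch(
        survival::survdiff(survival::Surv(rfs_months, event) ~ group,
                           data = sub),
        error = function(e) NULL)
      p <- if (is.null(sd) || !is.finite(sd$chisq)) NA_real_ else
        stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
      pw[i, j] <- pw[j, i] <- p
    }
  }
  structure(list(curves = curves, pairwise_p = pw, fit = fit),
            class = "km_result")
}

#' Write Kaplan-Meier curves to CSV
#'
#' @param km a [km_logrank()] result.
#' @param path output CSV path (columns group, time, n_risk, survival).
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(km, path) {
  utils::write.csv(km$curves, path, row.names = FALSE)
  invisible(path)
}

#' Stratify a continuous marker into tertile groups
#'
#' Splits values into three groups of as-equal-as-possible size (sizes
#' differ by at most one; the remainder goes to the lowest group, so 10
#' values split 4/3/3). Ties at group boundaries are broken by stable input
#' order. `NA` values stay `NA`.
#'
#' @param values numeric vector.
#' @return Factor with levels `low`, `medium`, `high`; attribute
#'   `degenerate` is `TRUE` when all values are equal.
#' @export
tertile_stratify <- function(values) {
  ok <- which(!is.na(values))
  n <- length(ok)
  out <- factor(rep(NA_character_, length(values)),
                levels = c("low", "medium", "high"))
  if (n == 0L) return(out)
  q <- n %/% 3L; rem <- n %% 3L
  sizes <- c(q + (rem >= 1), q + (rem >= 2), q)
  lab <- rep(c("low", "medium", "high"), times = sizes)
  out[ok[order(values[ok])]] <- lab
  degenerate <- length(unique(values[ok])) == 1L
  if (degenerate)
    warning("all marker values equal; tertile stratification is degenerate")
  attr(out, "degenerate") <- degenerate
  out
}

#' Combined 3-point recurrence risk score
#'
#' One point each for G3 tumor grade, a history of positive repeat
#' resection or recurrent tumor, and a medium-or-high immunodrop tertile.
#' Patients with 0 or 1 point form the low recurrence-risk group, 2 points
#' intermediate, 3 points high.
#'
#' @param grade tumor grade (`"G1"`/`"G2"`/`"G3"`, or a logical G3 flag).
#' @param retur_or_recurrent logical/0-1 history flag (positive repeat
#'   resection or recurrent tumor).
#' @param id_tertile immunodrop tertile (`"low"`/`"medium"`/`"high"`, as
#'   from [tertile_stratify()]).
#' @return Data frame with integer `points` (0-3) and factor `category`
#'   (`low`, `intermediate`, `high`).
#' @export
risk_score <- function(grade, retur_or_recurrent, id_tertile) {
  g3 <- if (is.logical(grade)) grade else as.character(grade) == "G3"
  hx <- as.logical(retur_or_recurrent)
  idm <- as.character(id_tertile) %in% c("medium", "high")
  points <- as.integer(g3) + as.integer(hx) + as.integer(idm)
  category <- cut(points, breaks = c(-1, 1, 2, 3),
                  labels = c("low", "intermediate", "high"))
  data.frame(points = points, category = category)
}
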