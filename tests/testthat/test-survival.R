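make_cohort <- function(n = 200, seed = 1, beta = NULL) {
  spec <- if (is.null(beta)) cohort_spec(n = n) else cohort_spec(n = n, beta = beta)
  simulate_cohort(spec, seed = seed)
}

test_that("follow-up beyond the horizon is administratively censored", {
  co <- data.frame(rfs_months = c(72, 16.6, 60, 59.9),
                   event = c(1L, 1L, 1L, 0L))
  cen <- censor_rfs(co, 60)
  expect_equal(cen$rfs_months, c(60, 16.6, 60, 59.9))
  expect_equal(cen$event, c(0L, 1L, 1L, 0L))
  expect_true(all(cen$rfs_months[cen$event == 1] <= 60))
  expect_identical(censor_rfs(co, Inf), co)
  expect_error(censor_rfs(co, 0), "positive")
  expect_error(censor_rfs(data.frame(rfs_months = -1, event = 0L)), "positive")
})

test_that("the train/test split is event-stratified and reproducible", {
  co <- make_cohort(157, seed = 3)
  sp <- split_cohort(co, 117, 40, seed = 11)
  expect_identical(nrow(sp$train), 117L)
  expect_identical(nrow(sp$test), 40L)
  # event proportions differ by less than one event's worth
  expect_lt(abs(mean(sp$train$event) - mean(sp$test$event)), 1 / 40)
  sp2 <- split_cohort(co, 117, 40, seed = 11)
  expect_identical(sp$train$patient, sp2$train$patient)
  sp3 <- split_cohort(co, 117, 40, seed = 12)
  expect_false(identical(sp$train$patient, sp3$train$patient))
  expect_error(split_cohort(co, 100, 40), "must equal")
  # degenerate all-event cohort still splits
  allev <- co; allev$event <- 1L
  spa <- split_cohort(allev, 117, 40, seed = 1)
  expect_true(all(spa$train$event == 1) && all(spa$test$event == 1))
})

test_that("Harrell's C matches the brute-force pairwise oracle exactly", {
  expect_equal(harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(harrell_c(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  set.seed(13)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    risks <- sample(round(rnorm(n), 2))        # some tied risks
    times <- sample(round(rexp(n, 0.1), 1))
    events <- rbinom(n, 1, 0.6)
    if (sum(events) == 0) events[1] <- 1L
    expect_identical(suppressWarnings(harrell_c(risks, times, events)),
                     oracle_harrell_c(risks, times, events))
  }
})

test_that("Harrell's C agrees with the survival package on tie-free data", {
  set.seed(21)
  n <- 150
  lp <- rnorm(n)
  times <- rexp(n, exp(lp) / 20)
  events <- rbinom(n, 1, 0.7)
  ours <- harrell_c(lp, times, events)
  ref <- survival::concordance(survival::Surv(times, events) ~ lp,
                               reverse = TRUE)$concordance
  expect_equal(ours, unname(ref))
})

test_that("univariable Cox recovers a known hazard ratio and flags degeneracies", {
  spec <- cohort_spec(n = 400, beta = c(g3 = log(2)))
  co <- simulate_cohort(spec, seed = 5)
  res <- univariable_cox(co, "g3")
  expect_false(res$flagged)
  ci <- exp(res$table$coef + c(-1.96, 1.96) * res$table$se)
  expect_true(ci[1] <= 2 && 2 <= ci[2])
  expect_equal(res$aic, 2 * 1 - 2 * res$loglik)
  # constant covariate is flagged, not fatal
  co$constant <- 1
  expect_true(univariable_cox(co, "constant")$flagged)
  expect_error(univariable_cox(co, "nope"), "unknown feature")
  # complete separation (a grade with zero events) is flagged, not a crash
  co2 <- co
  co2$rare <- co2$patient <= 5
  co2$event[co2$rare] <- 0L
  expect_silent(univariable_cox(co2, "rare"))
})

test_that("feature selection keeps strictly sub-alpha univariable results", {
  mk <- function(feature, p, flagged = FALSE) {
    structure(list(feature = feature, flagged = flagged,
                   table = data.frame(term = feature, p = p)),
              class = "cox_model_result")
  }
  res <- list(mk("a", 0.003), mk("b", 0.0126), mk("c", 0.051),
              mk("d", 0.05), mk("e", 0.001, flagged = TRUE))
  expect_identical(select_features(res), c("a", "b"))
  expect_identical(select_features(list()), character(0))
})

test_that("model enumeration lists every subset of size two or more", {
  expect_length(enumerate_models(c("a", "b", "c")), 4L)
  expect_length(enumerate_models(letters[1:6]), 57L)
  expect_length(enumerate_models("a"), 0L)
  expect_length(enumerate_models(character(0)), 0L)
  combos <- enumerate_models(c("a", "b", "c"))
  expect_true(list(c("a", "b", "c")) %in% combos ||
                any(vapply(combos, function(x) identical(x, c("a", "b", "c")),
                           logical(1))))
})

test_that("fit_and_filter keeps models whose covariates are all significant", {
  co <- make_cohort(400, seed = 7)
  co$noise <- rnorm(nrow(co))
  combos <- list(c("retur_or_recurrent", "g3", "id_value"),
                 c("retur_or_recurrent", "noise"),
                 c("retur_or_recurrent", "retur_or_recurrent2"))
  co$retur_or_recurrent2 <- co$retur_or_recurrent   # exact collinear duplicate
  kept <- fit_and_filter(co, combos)
  labels <- vapply(kept, `[[`, character(1), "feature")
  expect_true("retur_or_recurrent + g3 + id_value" %in% labels)
  expect_false("retur_or_recurrent + retur_or_recurrent2" %in% labels)
  expect_length(fit_and_filter(co, list()), 0L)
})

test_that("cross-validation scores held-out folds and rejects degenerate folds", {
  co <- make_cohort(200, seed = 9)
  cv <- cross_validate(co, c("retur_or_recurrent", "g3", "id_value"),
                       k = 5, seed = 2)
  expect_true(as.numeric(cv) > 0.5 && as.numeric(cv) < 1)
  expect_length(attr(cv, "fold_cindex"), 5L)
  cv2 <- cross_validate(co, c("retur_or_recurrent", "g3", "id_value"),
                        k = 5, seed = 2)
  expect_equal(as.numeric(cv), as.numeric(cv2))
  expect_error(cross_validate(co, "g3", k = nrow(co)), "comparable")
  expect_error(cross_validate(co, "g3", k = 1), ">= 2")
})

test_that("a perfectly separating risk score attains C = 1 in cross-validation", {
  n <- 100
  co <- data.frame(rfs_months = seq_len(n) + 0.5, event = 1L)
  co$marker <- -seq_len(n)                  # risk decreasing with time
  expect_equal(harrell_c(co$marker, co$rfs_months, co$event), 1)
  cv <- cross_validate(co, "marker", k = 5, seed = 3)
  expect_equal(as.numeric(cv), 1)
})

test_that("random risk scores concentrate near C = 0.5", {
  set.seed(31)
  cs <- replicate(40, {
    n <- 200
    times <- rexp(n, 0.05)
    events <- rbinom(n, 1, 0.5)
    suppressWarnings(harrell_c(rnorm(n), times, events))
  })
  expect_lt(abs(mean(cs) - 0.5), 0.02)
})

test_that("Kaplan-Meier without censoring equals the empirical survival function", {
  times <- c(1, 2, 2, 4, 7, 9)
  co <- data.frame(rfs_months = times, event = 1L)
  km <- km_logrank(co, rep("all", 6))
  ecdf_surv <- 1 - ecdf(times)(km$curves$time)
  expect_equal(km$curves$survival, ecdf_surv)
  # single-subject drop of 1/n per distinct event
  expect_equal(km$curves$survival[km$curves$time == 2], 3 / 6)
})

test_that("log-rank detects a strong group difference and respects the null", {
  set.seed(41)
  # power: hazard ratio 4 between two groups of 100
  p_alt <- replicate(20, {
    g <- rep(c(0, 1), each = 100)
    t <- rexp(200, 0.02 * 4^g)
    co <- data.frame(rfs_months = pmin(t, 60), event = as.integer(t <= 60))
    km_logrank(co, g)$pairwise_p[1, 2]
  })
  expect_gte(mean(p_alt < 0.05), 0.95)
  # null: two identical groups
  p_null <- replicate(200, {
    t <- rexp(100, 0.03)
    co <- data.frame(rfs_months = pmin(t, 60), event = as.integer(t <= 60))
    km_logrank(co, rep(c(0, 1), 50))$pairwise_p[1, 2]
  })
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.05)
})

test_that("tertile stratification balances group sizes and flags degeneracy", {
  t9 <- tertile_stratify(c(5, 1, 9, 3, 7, 2, 8, 4, 6))
  expect_equal(as.vector(table(t9)), c(3, 3, 3))
  expect_identical(as.character(t9[2]), "low")    # value 1
  expect_identical(as.character(t9[3]), "high")   # value 9
  t10 <- tertile_stratify(1:10)
  expect_equal(as.vector(table(t10)), c(4, 3, 3))
  expect_warning(td <- tertile_stratify(rep(2, 6)), "degenerate")
  expect_true(attr(td, "degenerate"))
  tna <- tertile_stratify(c(1, NA, 3, 2))
  expect_true(is.na(tna[2]))
})

test_that("the 3-point risk score maps all covariate combinations correctly", {
  combos <- expand.grid(g3 = c(FALSE, TRUE), hx = c(FALSE, TRUE),
                        idm = c(FALSE, TRUE))
  rs <- risk_score(ifelse(combos$g3, "G3", "G2"), combos$hx,
                   ifelse(combos$idm, "medium", "low"))
  expect_equal(rs$points, combos$g3 + combos$hx + combos$idm)
  expect_identical(as.character(rs$category),
                   c("low", "low", "intermediate", "high")[rs$points + 1])
  # spot checks of the published mapping
  expect_identical(as.character(risk_score("G3", TRUE, "high")$category),
                   "high")
  expect_identical(as.character(risk_score("G2", FALSE, "low")$category),
                   "low")
  expect_identical(as.character(risk_score("G3", FALSE, "low")$category),
                   "low")                          # one point is still low risk
  expect_equal(risk_score("G3", FALSE, "low")$points, 1)
})
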