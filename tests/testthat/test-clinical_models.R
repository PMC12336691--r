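test_that("carrier D-prime reproduces the published cohort values", {
  cc <- cohort_carrier_counts()
  dp <- carrier_dprime(cc$n, cc$nA, cc$nB, cc$nAB)
  expect_equal(round(dp, 2), c(0.27, 0.26, 0.14, 0.10, 0.31, 0.37))
})

test_that("carrier D-prime has the right boundary behaviour", {
  # exact independence: nAB = nA nB / n
  expect_equal(carrier_dprime(100, 40, 50, 20), 0)
  # complete association: nAB = min(nA, nB)
  expect_equal(carrier_dprime(100, 40, 50, 40), 1)
  # negative disequilibrium is normalized by its own maximum
  expect_equal(carrier_dprime(100, 50, 50, 0), 1)
  expect_error(carrier_dprime(100, 0, 50, 0), "degenerate")
  expect_error(carrier_dprime(100, 40, 50, 45), "inconsistent")
})

test_that("exact matching retains only strata with both groups", {
  meta <- tibble::tibble(
    subject_id = sprintf("p%02d", 1:8),
    grp = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    age = c(30, 31, 50, 51, 30, 40, 41, 70),
    sex = c("f", "f", "m", "m", "f", "f", "f", "m"),
    carrier_A = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    carrier_B = FALSE)
  m <- exact_match(meta, "grp", vars = c("sex", "carrier_A"))
  # stratum (m, FALSE) has both groups; (f, TRUE) has both; p6/p7 (f,
  # FALSE) both; p8 (m, TRUE) is a one-group stratum and is dropped
  expect_false("p08" %in% m$matched$subject_id)
  expect_true(all(c("p01", "p02", "p03", "p04") %in%
                    m$matched$subject_id))
  # identical groups: everyone retained
  meta2 <- meta
  meta2$sex <- "f"; meta2$carrier_A <- TRUE; meta2$age <- 40
  m2 <- exact_match(meta2, "grp", vars = c("sex", "carrier_A"))
  expect_equal(nrow(m2$matched), nrow(meta2))
})

test_that("matching balances the matching variables", {
  set.seed(91)
  n <- 600
  grp <- rep(c(TRUE, FALSE), c(200, 400))
  # planted imbalance: treated subjects older and more often carriers
  age <- ifelse(grp, rnorm(n, 45, 8), rnorm(n, 38, 8))
  carrier_A <- runif(n) < ifelse(grp, 0.5, 0.25)
  meta <- tibble::tibble(subject_id = seq_len(n), grp = grp, age = age,
                         sex = sample(c("f", "m"), n, TRUE),
                         carrier_A = carrier_A, carrier_B = FALSE)
  m <- exact_match(meta, "grp", age_bins = 8L)
  d <- m$matched
  wmean <- function(x, g) sum(x[g] * d$weight[g]) / sum(d$weight[g])
  # exact categorical variables balance exactly under matching weights
  smd <- abs(wmean(d$carrier_A, d$grp) - wmean(d$carrier_A, !d$grp))
  expect_lt(smd, 1e-10)
  smd_age <- abs(wmean(d$age, d$grp) - wmean(d$age, !d$grp)) / sd(d$age)
  expect_lt(smd_age, 0.15)   # binned age: residual within-bin drift only
})

test_that("linear interaction fits equal the normal-equation oracle", {
  set.seed(92)
  d <- tibble::tibble(
    age = c(30, 40, 50, 35, 45, 55, 32, 48, 60, 38),
    sex = c("f", "f", "m", "m", "f", "m", "m", "f", "f", "m"),
    disease_duration = c(1, 3, 5, 2, 8, 4, 6, 7, 2, 3),
    ga = rep(c(TRUE, FALSE), each = 5),
    carrier_A = c(TRUE, FALSE, TRUE, FALSE, TRUE,
                  FALSE, TRUE, FALSE, TRUE, FALSE),
    carrier_B = c(FALSE, TRUE, TRUE, TRUE, FALSE,
                  TRUE, FALSE, FALSE, FALSE, TRUE),
    y = rnorm(10))
  fit <- fit_linear_interaction(d, "y", treatment = "ga")
  X <- stats::model.matrix(
    y ~ age_norm + sexm + duration_norm + ga + carrier_A + carrier_B +
      ga:carrier_A + ga:carrier_B,
    transform(d, age_norm = min_max_scale(age),
              duration_norm = min_max_scale(disease_duration),
              sexm = sex == "m"))
  beta <- solve(crossprod(X), crossprod(X, d$y))
  expect_equal(unname(fit$coefficients$estimate), unname(beta[, 1]),
               tolerance = 1e-10)
  # a collinear design is refused with the offending column named
  d2 <- d; d2$carrier_B <- d2$carrier_A
  expect_error(fit_linear_interaction(d2, "y"), "collinear")
})

test_that("planted linear interaction effects are recovered unbiasedly", {
  cfg <- generator_config()
  ests <- vapply(1:8, function(s) {
    meta <- gen_trial_meta(list(IFN = c(165, 74), GA = c(64, 32)), cfg,
                           seed = 100 + s)
    sim <- gen_clinical(meta, cfg, seed = 100 + s)
    d <- dplyr::inner_join(sim$continuous, meta, by = "subject_id")
    d$ga <- d$treatment_arm == "GA"
    fit <- fit_linear_interaction(d, "delta_edss", treatment = "ga")
    fit$coefficients$estimate[fit$coefficients$term ==
                                "gaTRUE:carrier_ATRUE"]
  }, numeric(1))
  planted <- unname(cfg$clinical$beta_edss["inter_ga_A"])
  expect_lt(abs(mean(ests) - planted), 2 * sd(ests) / sqrt(length(ests)) +
              0.05)
})

test_that("Cox fits approximate the exponential rate-ratio oracle", {
  set.seed(93)
  n <- 4000
  x <- rep(c(0, 1), each = n / 2)
  time <- rexp(n, 0.2 * exp(log(0.5) * x))
  d <- tibble::tibble(time = time, status = 1L, x = x)
  fit <- fit_cox(d, "x")
  expect_equal(unname(fit$coefficients$hr), 0.5, tolerance = 0.1)
  d$const <- 1
  expect_error(fit_cox(d, c("x", "const")), "constant")
  d0 <- d; d0$status <- 0L
  expect_error(fit_cox(d0, "x"), "no events")
})

test_that("the partial likelihood equals brute-force enumeration on 6 subjects", {
  # distinct event times, one censoring, one binary covariate
  d <- tibble::tibble(
    time = c(2, 4, 5, 7, 9, 11),
    status = c(1L, 1L, 0L, 1L, 1L, 1L),
    x = c(1, 0, 1, 1, 0, 0))
  pl <- function(beta) {
    # product over events of exp(b x_i) / sum_{j at risk} exp(b x_j)
    ll <- 0
    for (i in which(d$status == 1L)) {
      risk <- d$time >= d$time[i]
      ll <- ll + beta * d$x[i] - log(sum(exp(beta * d$x[risk])))
    }
    ll
  }
  fit <- fit_cox(d, "x")
  bhat <- fit$coefficients$estimate
  expect_equal(fit$fit$loglik[2], pl(bhat), tolerance = 1e-8)
  # the brute-force maximizer agrees with the fitted coefficient
  opt <- stats::optimize(pl, c(-5, 5), maximum = TRUE)
  expect_equal(bhat, opt$maximum, tolerance = 1e-4)
  # likelihood evaluated away from the optimum also agrees
  f0 <- survival::coxph(survival::Surv(time, status) ~ x, data = d,
                        init = 0.7,
                        control = survival::coxph.control(iter.max = 0))
  expect_equal(f0$loglik[2], pl(0.7), tolerance = 1e-8)
})

test_that("Andersen-Gill reduces to the first-event Cox on single intervals", {
  set.seed(94)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  time <- ceiling(rexp(n, 0.3 * exp(0.5 * x)) * 100)
  status <- as.integer(time < 200)
  time <- pmin(time, 200)
  d1 <- tibble::tibble(time = time, status = status, x = x,
                       subject_id = sprintf("p%03d", 1:n))
  dag <- tibble::tibble(start = 0, stop = time, event = status, x = x,
                        subject_id = d1$subject_id)
  f1 <- fit_cox(d1, "x")
  f2 <- fit_cox_ag(dag, "x")
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-8)
  # overlapping intervals are a data error
  bad <- tibble::tibble(start = c(0, 5), stop = c(10, 12),
                        event = c(1L, 0L), x = 1:2 * 0,
                        subject_id = "p1")
  expect_error(fit_cox_ag(bad, "x"), "overlapping")
})

test_that("robust clustered SEs exceed naive SEs under correlation", {
  set.seed(95)
  n <- 150
  x <- rbinom(n, 1, 0.5)
  frail <- rgamma(n, 2, 2)        # shared within-subject frailty
  rows <- lapply(1:n, function(i) {
    k <- rpois(1, 2 * frail[i])
    times <- sort(runif(k, 1, 364))
    tibble::tibble(subject_id = sprintf("p%03d", i),
                   start = c(0, times), stop = c(times, 365),
                   event = c(rep(1L, k), 0L), x = x[i])
  })
  d <- dplyr::bind_rows(rows)
  fit <- fit_cox_ag(d, "x")
  expect_gt(fit$coefficients$se, fit$coefficients$naive_se)
})

test_that("Schoenfeld residuals vanish at the MPLE and flag non-proportionality", {
  set.seed(96)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  d <- tibble::tibble(time = rexp(n, 0.2 * exp(0.4 * x)), status = 1L,
                      x = x)
  fit <- fit_cox(d, "x")
  res <- schoenfeld_residuals(fit)
  expect_lt(abs(sum(res$x)), 1e-6)
  # proportional hazards: no residual-time trend
  expect_lt(abs(cor(res$time, res$x)), 0.12)
  # a strongly time-varying effect leaves a trend
  tv <- tibble::tibble(
    time = c(rexp(n / 2, exp(2 * x[1:(n / 2)])),
             5 + rexp(n / 2, exp(-2 * x[(n / 2 + 1):n]))),
    status = 1L, x = x)
  res_tv <- schoenfeld_residuals(fit_cox(tv, "x"))
  expect_gt(abs(cor(res_tv$time, res_tv$x)), 0.15)
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  # 5 subjects: events at 2, 4, 7, 9; censored at 5
  d <- tibble::tibble(time = c(2, 4, 5, 7, 9),
                      status = c(1L, 1L, 0L, 1L, 1L))
  km <- kaplan_meier(d)
  s_hand <- cumprod(c(1 - 1 / 5, 1 - 1 / 4, 1, 1 - 1 / 2, 1 - 1 / 1))
  expect_equal(km$surv, s_hand)
  # no events: flat at 1
  km0 <- kaplan_meier(tibble::tibble(time = c(3, 6), status = 0L))
  expect_true(all(km0$surv == 1))
  # all events, distinct times: empirical survival function
  de <- tibble::tibble(time = 1:4, status = 1L)
  expect_equal(kaplan_meier(de)$surv, c(0.75, 0.5, 0.25, 0))
})
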