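test_that("waiting-time extraction anchors on the first activation", {
  rec <- tibble::tibble(nucleus_id = c("a", "b", "c"),
                        movie_id = "m1",
                        mother_state = "active",
                        t_activation = c(5, 7, 9) * 60,
                        t_end = 1800)
  wts <- extract_waiting_times(rec)
  expect_equal(attr(wts, "T0"), 300)
  expect_equal(sort(wts$time), c(0, 120, 240))

  # censored nucleus carries t_end - T0
  rec2 <- dplyr::bind_rows(rec, tibble::tibble(
    nucleus_id = "d", movie_id = "m1", mother_state = "active",
    t_activation = NA_real_, t_end = 1800))
  wts2 <- extract_waiting_times(rec2)
  expect_equal(wts2$time[wts2$status == 0], 1500)

  # per-movie mode shifts each movie by its own first activation
  rec3 <- dplyr::bind_rows(
    rec, dplyr::mutate(rec, movie_id = "m2", t_activation = t_activation + 60))
  wts3 <- extract_waiting_times(rec3, t0_mode = "per_movie")
  expect_equal(sort(wts3$time[wts3$movie_id == "m2"]), c(0, 120, 240))

  allc <- dplyr::mutate(rec, t_activation = NA_real_)
  expect_error(extract_waiting_times(allc), class = "mitobook_extraction_error")
})

test_that("Kaplan-Meier matches the empirical and oracle estimates", {
  wts <- tibble::tibble(time = c(1, 2, 3), status = 1L)
  km <- kaplan_meier(wts)
  expect_equal(km$time, c(0, 1, 2, 3))
  expect_equal(km$surv, c(1, 2 / 3, 1 / 3, 0))

  # all censored: survival stays at 1
  cens <- tibble::tibble(time = rep(10, 4), status = 0L)
  expect_true(all(kaplan_meier(cens)$surv == 1))

  set.seed(51)
  for (i in 1:15) {
    n <- sample(20:60, 1)
    tm <- rexp(n, 1 / 50)
    st <- as.integer(runif(n) > 0.3)
    if (!any(st == 1)) st[1] <- 1L
    km <- kaplan_meier(tibble::tibble(time = tm, status = st))
    want <- oracle_km(tm, st)
    got <- km[km$time %in% want$time & km$n_event > 0, ]
    expect_equal(got$surv, want$surv, tolerance = 1e-12)
  }
})

test_that("mixed-Gamma survival matches its defining identities", {
  p <- c(0.3, 0.4, 0.3)
  expect_equal(survival_model(0, p, 100), 1)
  # exponential component half-life
  expect_equal(survival_model(100 * log(2), c(1, 0, 0), 100), 0.5)
  # mean integral identity: integral of S = a * b
  set.seed(52)
  for (i in 1:10) {
    pr <- runif(3)
    pr <- pr / sum(pr)
    tau <- runif(1, 20, 300)
    a <- sum(seq_along(pr) * pr)
    integral <- integrate(function(t) survival_model(t, pr, tau), 0, Inf,
                          rel.tol = 1e-9)$value
    expect_equal(integral, a * tau, tolerance = 1e-6)
  }
  expect_error(survival_model(1, c(0.5, 0.2), 10),
               class = "mitobook_input_error")
})

test_that("survival fitting recovers generative mixtures", {
  # dense noiseless curve
  tgrid <- seq(1, 1500, by = 2)
  curve <- tibble::tibble(time = tgrid,
                          surv = survival_model(tgrid, c(0.3, 0.4, 0.3), 100))
  fit <- fit_survival(curve)
  expect_lt(max(abs(fit$p - c(0.3, 0.4, 0.3))), 0.02)
  expect_lt(abs(fit$tau - 100) / 100, 0.02)
  expect_equal(fit$b, fit$tau)
  expect_equal(fit$a, sum(seq_along(fit$p) * fit$p))

  # pure-exponential limit
  ecurve <- tibble::tibble(time = tgrid,
                           surv = survival_model(tgrid, c(1, 0, 0), 120))
  efit <- fit_survival(ecurve)
  expect_gte(efit$a, 0.95)
  expect_lte(efit$a, 1.1)

  expect_error(fit_survival(tibble::tibble(time = c(1, 2), surv = c(0.7, 0.3))),
               class = "mitobook_fit_error")
})

test_that("moment-based state counting returns shape + 1", {
  set.seed(53)
  g3 <- rgamma(2e4, shape = 3, scale = 80)
  expect_equal(estimate_states(g3)$N_rounded, 4L)
  ex <- rexp(2e4, 1 / 80)
  expect_equal(estimate_states(ex)$N_rounded, 2L)
  # additive shift inflates the moment estimate
  shifted <- estimate_states(ex + 160)
  expect_gt(shifted$a_mv, estimate_states(ex)$a_mv + 1)
  expect_error(estimate_states(rep(5, 10)), class = "mitobook_input_error")
})

test_that("memory scores compare subpopulation mean waiting times", {
  mk <- function(a, b) structure(list(a = a, b = b), class = "memory_fit")
  expect_equal(memory_score(mk(2, 100), mk(2, 100)),
               tibble::tibble(score_ab = 1, score_b = 1))
  sc <- memory_score(mk(2, 200), mk(2, 100))
  expect_equal(sc$score_ab, 2)
  expect_equal(sc$score_b, 2)
})

test_that("chain simulation matches the closed-form survival", {
  rec <- simulate_chain(c(1, 0, 0), 100, 5000, seed = 55)
  wts <- extract_waiting_times(rec)
  # T0 subtraction removes only the minimum; mean of Tr ~ tau
  expect_lt(abs(mean(wts$time) - 100) / 100, 0.05)

  rec2 <- simulate_chain(c(0.3, 0.4, 0.3), 100, 5000, seed = 56)
  S_emp <- function(t) mean(rec2$t_activation > t)
  tg <- seq(0, 2000, by = 10)
  sup <- max(abs(vapply(tg, S_emp, numeric(1)) -
                 survival_model(tg, c(0.3, 0.4, 0.3), 100)))
  expect_lt(sup, 0.03)

  expect_identical(simulate_chain(c(0.5, 0.5), 50, 100, seed = 7),
                   simulate_chain(c(0.5, 0.5), 50, 100, seed = 7))

  # censoring at t_end
  rec3 <- simulate_chain(c(1, 0, 0), 100, 2000, T0 = 0, t_end = 150, seed = 57)
  expect_true(all(is.na(rec3$t_activation) | rec3$t_activation <= 150))
  expect_gt(sum(is.na(rec3$t_activation)), 0)
})

test_that("cumulative activation yields the t50 of the active pattern", {
  rec <- tibble::tibble(t_activation = c(2, 4, 6, 8))
  cum <- cumulative_activation(rec)
  expect_equal(attr(cum, "t50"), 4)
  expect_true(all(diff(cum$frac_activated) >= 0))
  expect_equal(dplyr::last(cum$frac_activated), 1)

  single <- cumulative_activation(tibble::tibble(t_activation = 7))
  expect_equal(attr(single, "t50"), 7)
})

test_that("fit objects print, tidy and plot", {
  tgrid <- seq(1, 1500, by = 5)
  fit <- fit_survival(tibble::tibble(
    time = tgrid, surv = survival_model(tgrid, c(0.3, 0.4, 0.3), 100)))
  expect_output(print(fit), "Mixed-Gamma")
  expect_equal(sum(tidy(fit)$estimate[1:3]), 1, tolerance = 1e-6)
  expect_equal(glance(fit)$mean_waiting, fit$a * fit$b)
  expect_s3_class(autoplot(fit), "ggplot")
})
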