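#' Extract post-mitotic waiting times from activation records
#'
#' The post-mitotic activation delay decomposes as `T_a = T_0 + T_r`: a
#' deterministic incompressible lag `T_0`, set to the instant the first
#' nucleus activates, plus a stochastic waiting time `T_r`. Records are
#' split by the transcriptional state of the mother nucleus in the previous
#' cycle, the grouping on which the memory comparison rests.
#'
#' @param records Tibble with columns `nucleus_id`, `movie_id`,
#'   `mother_state` (`"active"`, `"inactive"` or `"unknown"`),
#'   `t_activation` (s from anaphase onset; `NA` = censored) and `t_end`
#'   (movie end, s).
#' @param t0_mode `"pooled"` (default: one `T_0` across movies) or
#'   `"per_movie"` (each movie shifted by its own first activation).
#' @return Tibble with columns `nucleus_id`, `movie_id`, `mother_state`,
#'   `time` (`T_r`, or censoring time for censored nuclei) and `status`
#'   (1 = activation observed, 0 = censored). `T_0` is attached as attribute
#'   `"T0"` (named vector in per-movie mode).
#' @export
extract_waiting_times <- function(records, t0_mode = c("pooled", "per_movie")) {
  t0_mode <- match.arg(t0_mode)
  assert_cols(records, c("nucleus_id", "movie_id", "mother_state",
                         "t_activation", "t_end"), "activation records")
  if (all(is.na(records$t_activation))) {
    abort("all records are censored; cannot set T0",
          class = "mitobook_extraction_error")
  }
  records <- as_tibble(records)
  if (t0_mode == "pooled") {
    T0 <- min(records$t_activation, na.rm = TRUE)
    records$t0 <- T0
  } else {
    t0s <- records |>
      group_by(.data$movie_id) |>
      summarise(t0 = min(.data$t_activation, na.rm = TRUE))
    records <- left_join(records, t0s, by = "movie_id")
    T0 <- setNames(t0s$t0, t0s$movie_id)
  }
  out <- records |>
    mutate(status = ifelse(is.na(.data$t_activation), 0L, 1L),
           time = ifelse(.data$status == 1L,
                         .data$t_activation - .data$t0,
                         .data$t_end - .data$t0)) |>
    select("nucleus_id", "movie_id", "mother_state", "time", "status")
  if (any(out$time < 0)) {
    abort("negative waiting time: t_end or t_activation before T0",
          class = "mitobook_extraction_error")
  }
  attr(out, "T0") <- T0
  out
}

#' Kaplan-Meier survival curve of waiting times
#'
#' Product-limit estimate of `S(t) = P(T_r > t)` with right censoring of
#' never-activated nuclei (drop them instead with `censoring = "drop"`).
#' Without censoring this is the empirical fraction of waiting times above
#' `t`.
#'
#' @param wts Waiting-time tibble from [extract_waiting_times()] (columns
#'   `time`, `status`), typically pre-filtered to one `mother_state`.
#' @param censoring `"km"` (default) or `"drop"`.
#' @return Tibble of class `survival_curve` with columns `time`, `surv`,
#'   `n_risk`, `n_event`, starting at `time = 0`, `surv = 1`.
#' @export
kaplan_meier <- function(wts, censoring = c("km", "drop")) {
  censoring <- match.arg(censoring)
  assert_cols(wts, c("time", "status"), "waiting times")
  if (censoring == "drop") wts <- filter(wts, .data$status == 1L)
  if (nrow(wts) == 0L) stop_input("no observations left after dropping censored records")
  sf <- survival::survfit(survival::Surv(time, status) ~ 1,
                          data = as.data.frame(wts))
  out <- tibble(time = c(0, sf$time), surv = c(1, sf$surv),
                n_risk = c(sf$n, sf$n.risk), n_event = c(0L, sf$n.event))
  class(out) <- c("survival_curve", class(out))
  out
}

#' Mixed-Gamma survival function of the linear irreversible chain
#'
#' Theoretical survival of the waiting time through a linear, irreversible
#' continuous-time Markov chain with three OFF states of common lifetime
#' `tau` and mixing weights `p = (p1, p2, p3)` over the number of jumps to
#' reach ON:
#' \deqn{S(t) = p_1 e^{-t/\tau} + p_2 (1 - \gamma(2, t/\tau)/\Gamma(2)) +
#'   p_3 (1 - \gamma(3, t/\tau)/\Gamma(3)),}
#' i.e. a mixture of Gamma(k, tau) upper tails, k = 1..3. Generalizes to any
#' number of states via `length(p)`.
#'
#' @param t Times (s, >= 0).
#' @param p Mixing probabilities (nonnegative, sum to 1).
#' @param tau Common OFF-state lifetime (s, > 0).
#' @return `S(t)` values.
#' @export
survival_model <- function(t, p, tau) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop_input("`p` must be nonnegative and sum to 1")
  }
  if (tau <= 0) stop_input("`tau` must be > 0")
  S <- 0
  for (k in seq_along(p)) {
    S <- S + p[[k]] * stats::pgamma(t / tau, shape = k, lower.tail = FALSE)
  }
  S
}

#' Fit the mixed-Gamma survival model to an empirical curve
#'
#' Minimizes the sum of squared differences
#' `O = sum_j (S_exp(t_j) - S(t_j))^2` over the event times of the empirical
#' Kaplan-Meier curve, with the mixing weights on the probability simplex
#' (softmax reparameterization) and `tau > 0` (log-parameterized).
#' Optimization is Nelder-Mead from a deterministic multi-start grid. The
#' summary parameters are `a = p1 + 2 p2 + 3 p3` (mean number of jumps) and
#' `b = tau`, so the mean waiting time is `a * b`.
#'
#' @param curve Survival curve from [kaplan_meier()].
#' @param n_states Chain size (default 4 = 3 OFF states + ON, the selected
#'   model; larger values are available as a robustness check).
#' @return Object of class `memory_fit` with elements `p`, `tau`, `a`, `b`,
#'   `O` (cost at optimum) and `n_states`.
#' @export
fit_survival <- function(curve, n_states = 4) {
  assert_cols(curve, c("time", "surv"), "survival curve")
  pts <- filter(as_tibble(curve), .data$time > 0)
  if (nrow(pts) < 4L) stop_fit("need at least 4 event times to fit")
  t_j <- pts$time
  s_j <- pts$surv
  n_p <- n_states - 1L
  cost <- function(theta) {
    z <- c(theta[seq_len(n_p - 1L)], 0)
    p <- exp(z - max(z))
    p <- p / sum(p)
    tau <- exp(theta[[n_p]])
    sum((s_j - survival_model(t_j, p, tau))^2)
  }
  mean_t <- sum(diff(c(0, t_j)) * s_j)  # crude integral of the step curve
  starts <- list()
  for (ltau in log(pmax(mean_t, 1e-6) * c(0.3, 1))) {
    for (zlead in list(rep(0, n_p - 1L), c(rep(1.5, 1), rep(0, n_p - 2L)),
                       c(rep(0, n_p - 2L), 1.5))) {
      starts[[length(starts) + 1L]] <- c(zlead, ltau)
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- optim(st, cost, method = "Nelder-Mead",
                 control = list(maxit = 1500, reltol = 1e-11))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  z <- c(best$par[seq_len(n_p - 1L)], 0)
  p <- exp(z - max(z))
  p <- p / sum(p)
  tau <- exp(best$par[[n_p]])
  a <- sum(seq_along(p) * p)
  structure(list(p = p, tau = tau, a = a, b = tau, O = best$value,
                 n_states = n_states,
                 data = tibble(time = t_j, surv = s_j,
                               fitted = survival_model(t_j, p, tau))),
            class = "memory_fit")
}

#' @export
print.memory_fit <- function(x, ...) {
  cat("Mixed-Gamma memory fit (n_states = ", x$n_states, ")\n", sep = "")
  cat("  p = (", paste(sprintf("%.3f", x$p), collapse = ", "), ")\n", sep = "")
  cat(sprintf("  tau = %.4g s  a = %.3f  b = %.4g s  mean T_r = %.4g s\n",
              x$tau, x$a, x$b, x$a * x$b))
  cat(sprintf("  cost O = %.4g\n", x$O))
  invisible(x)
}

#' Tidy a memory-model fit
#'
#' @param x A `memory_fit` object.
#' @param ... Unused.
#' @export
tidy.memory_fit <- function(x, ...) {
  tibble(term = c(paste0("p", seq_along(x$p)), "tau", "a", "b"),
         estimate = c(x$p, x$tau, x$a, x$b))
}

#' @rdname tidy.memory_fit
#' @export
glance.memory_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, mean_waiting = x$a * x$b, O = x$O,
         n_states = x$n_states)
}

#' Plot a memory-model fit over the empirical survival curve
#'
#' @param object A `memory_fit` object.
#' @param ... Unused.
#' @export
autoplot.memory_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$time)) +
    geom_step(aes(y = .data$surv)) +
    geom_line(aes(y = .data$fitted), colour = "firebrick") +
    labs(x = "waiting time T_r (s)", y = "S(t)") +
    theme_minimal()
}

#' Moment estimate of the number of chain states
#'
#' From observed waiting times, `a = M^2 / V` (squared mean over variance)
#' estimates the mean number of jumps of a homogeneous linear chain, and the
#' number of states is `N = a + 1`. A constant additive shift of the data
#' inflates the estimate, which is why `T_0` must be removed first.
#'
#' @param Tr Observed (uncensored) waiting times, length >= 2.
#' @return One-row tibble with `a_mv`, `N`, `N_rounded`.
#' @export
estimate_states <- function(Tr) {
  Tr <- Tr[!is.na(Tr)]
  if (length(Tr) < 2L) stop_input("need at least 2 observed waiting times")
  V <- var(Tr)
  if (V == 0) stop_input("zero variance in waiting times")
  a_mv <- mean(Tr)^2 / V
  tibble(a_mv = a_mv, N = a_mv + 1, N_rounded = as.integer(round(a_mv + 1)))
}

#' Transcriptional memory score
#'
#' Ratio of the fitted mean waiting times of daughters of inactive versus
#' active mothers: `score_ab = (a_in * b_in) / (a_act * b_act)`, with the
#' lifetime-only variant `score_b = b_in / b_act`. A ratio above 1 indicates
#' a memory bias (daughters of active mothers reactivate faster).
#'
#' @param fit_from_inactive,fit_from_active `memory_fit` objects for the two
#'   subpopulations.
#' @return One-row tibble with `score_ab` and `score_b`.
#' @export
memory_score <- function(fit_from_inactive, fit_from_active) {
  denom_ab <- fit_from_active$a * fit_from_active$b
  if (denom_ab == 0 || fit_from_active$b == 0) stop_input("zero denominator in score")
  tibble(score_ab = (fit_from_inactive$a * fit_from_inactive$b) / denom_ab,
         score_b = fit_from_inactive$b / fit_from_active$b)
}

#' Simulate waiting times from the linear irreversible chain
#'
#' For each nucleus the number of jumps `k` is drawn with probability `p_k`
#' and `T_r` is the sum of `k` independent exponential lifetimes of mean
#' `tau` (a Gamma(k, tau) variate); `t_activation = T_0 + T_r`, censored at
#' `t_end`.
#'
#' @param p Jump-count probabilities.
#' @param tau Common OFF-state lifetime (s).
#' @param n Number of nuclei.
#' @param T0 Deterministic lag added to every waiting time (s).
#' @param t_end Movie end; activations after it are censored (default `Inf`).
#' @param seed Seed for reproducibility (optional).
#' @param movie_id Movie label for the records.
#' @param mother_state Mother-state label for the records.
#' @return Activation-record tibble as accepted by
#'   [extract_waiting_times()].
#' @export
simulate_chain <- function(p, tau, n, T0 = 0, t_end = Inf, seed = NULL,
                           movie_id = "sim", mother_state = "unknown") {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) stop_input("invalid `p`")
  if (tau <= 0) stop_input("`tau` must be > 0")
  with_stream_seed(seed, paste0("chain/", movie_id, "/", mother_state), {
    k <- sample.int(length(p), n, replace = TRUE, prob = p)
    Tr <- rgamma(n, shape = k, scale = tau)
    t_act <- T0 + Tr
    tibble(nucleus_id = sprintf("%s_n%04d", movie_id, seq_len(n)),
           movie_id = movie_id,
           mother_state = mother_state,
           t_activation = ifelse(t_act <= t_end, t_act, NA_real_),
           t_end = t_end)
  })
}

#' Cumulative activation curve and t50
#'
#' Fraction of eventually-active nuclei activated by time `t`, and the
#' earliest time at which that fraction reaches 50% (`t50`), the summary
#' used to compare activation speed across genotypes.
#'
#' @param records Activation-record tibble.
#' @param t_grid Evaluation times; defaults to the sorted observed
#'   activation times.
#' @return Tibble with columns `time` and `frac_activated`; `t50` is
#'   attached as attribute `"t50"`.
#' @export
cumulative_activation <- function(records, t_grid = NULL) {
  assert_cols(records, c("t_activation"), "activation records")
  obs <- sort(records$t_activation[!is.na(records$t_activation)])
  if (length(obs) == 0L) stop_input("no observed activations")
  t_grid <- t_grid %||% unique(obs)
  frac <- vapply(t_grid, function(tt) sum(obs <= tt), numeric(1)) / length(obs)
  out <- tibble(time = t_grid, frac_activated = frac)
  reached <- which(frac >= 0.5)
  attr(out, "t50") <- if (length(reached)) t_grid[[min(reached)]] else NA_real_
  out
}
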