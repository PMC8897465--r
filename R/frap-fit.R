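#' Fit the reaction-diffusion model to a normalized FRAP trace
#'
#' Bounded nonlinear least squares of [frap_model()] against the
#' post-bleach portion of a normalized trace (first `fit_frames` post-bleach
#' frames, 1100 by default — the published fitting window). Free parameters
#' are `K`, `M` (box `[0.9, 1.1]`, constraining the mobile fraction so the
#' bound fraction is not absorbed into immobile signal), `tau`, `F_eq` (box
#' `[0, 1]`), `k_off` and `F_inf`. `M` is initialized from the mobile-fraction
#' relation `M = (I_plateau - I_0) / (1 - I_0)` with the plateau estimated
#' from samples at `t > 30 tau_init`; a deterministic multi-start grid over
#' `(tau, k_off, F_eq)` guards against local minima and the best
#' sum-of-squares fit is kept.
#'
#' The amplitude parameters `M`, `F_eq` and `F_inf` are algebraically
#' degenerate when all three are free (the model's constant term is fixed by
#' its two amplitude terms), so by default the exchange asymptote is pinned
#' at `F_inf = 1` — complete long-time recovery — which makes the remaining
#' parameters identifiable. Set `fix_F_inf = NULL` to fit it freely as a
#' robustness check (parameter values then lie on a ridge even though the
#' curve is well determined).
#'
#' @param trace Normalized trace from [frap_normalize()] (or any tibble with
#'   `time` and `i_norm`).
#' @param fit_frames Number of post-bleach frames to fit (default 1100).
#' @param n_prebleach Number of pre-bleach frames (default taken from the
#'   trace attribute, else 10).
#' @param variant Series variant passed to [frap_model()].
#' @param fix_F_inf Value at which to pin the exchange asymptote (default 1),
#'   or `NULL` to fit it.
#' @param init Optional named list overriding starting values.
#' @return Object of class `frap_fit`; see [tidy.frap_fit()],
#'   [glance.frap_fit()] and [autoplot.frap_fit()].
#' @export
fit_frap <- function(trace, fit_frames = 1100, n_prebleach = NULL,
                     variant = c("literal", "standard_axelrod"),
                     fix_F_inf = 1, init = NULL) {
  variant <- match.arg(variant)
  assert_cols(trace, c("time", "i_norm"), "normalized FRAP trace")
  n_prebleach <- n_prebleach %||% attr(trace, "n_prebleach") %||% 10L
  bleach_index <- n_prebleach + 1L
  if (nrow(trace) < bleach_index + 10L) {
    stop_input("trace too short: need at least 10 post-bleach frames")
  }
  post <- trace[seq(bleach_index, min(nrow(trace), bleach_index + fit_frames - 1L)), ]
  t <- post$time - post$time[[1]]
  y <- post$i_norm
  t_span <- max(t)

  I0 <- y[[1]]
  K_init <- if (I0 > 0 && I0 < 0.999) {
    uniroot(function(K) (1 - exp(-K)) / K - I0, c(1e-4, 50))$root
  } else 1
  lower <- c(K = 1e-4, M = 0.9, tau = 1e-4, F_eq = 0, k_off = 1e-6, F_inf = 0)
  upper <- c(K = 50, M = 1.1, tau = 10 * t_span, F_eq = 1, k_off = 1e3, F_inf = 2)
  free <- names(lower)
  if (!is.null(fix_F_inf)) free <- setdiff(free, "F_inf")

  starts <- list()
  for (tau0 in t_span * c(0.002, 0.02, 0.2)) {
    for (koff0 in c(10, 1, 0.1) / t_span) {
      for (feq0 in c(0.2, 0.5, 0.8)) {
        plateau0 <- if (any(t > 30 * tau0)) mean(y[t > 30 * tau0]) else mean(tail(y, 10))
        M0 <- min(max((plateau0 - I0) / (1 - I0), 0.9), 1.1)
        if (!is.finite(M0)) M0 <- 1
        st <- c(K = K_init, M = M0, tau = tau0, F_eq = feq0,
                k_off = koff0, F_inf = 1)
        if (!is.null(init)) st[names(init)] <- unlist(init)
        st <- pmin(pmax(st, lower), upper)
        starts[[length(starts) + 1L]] <- st[free]
      }
    }
  }

  resid_fn <- function(par) {
    F_inf <- if (is.null(fix_F_inf)) par[["F_inf"]] else fix_F_inf
    frap_model(t, K = par[["K"]], M = par[["M"]], tau = par[["tau"]],
               F_eq = par[["F_eq"]], k_off = par[["k_off"]],
               F_inf = F_inf, variant = variant) - y
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower[free], upper = upper[free],
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    stop_fit("FRAP fit failed to converge from every start",
             diagnostics = list(n_starts = length(starts)))
  }
  par <- coef(best$fit)
  if (!is.null(fix_F_inf)) par[["F_inf"]] <- fix_F_inf
  fitted <- frap_model(t, par[["K"]], par[["M"]], par[["tau"]], par[["F_eq"]],
                       par[["k_off"]], par[["F_inf"]], variant = variant)
  plateau <- if (any(t > 30 * par[["tau"]])) mean(y[t > 30 * par[["tau"]]]) else mean(tail(y, 10))
  structure(list(
    K = par[["K"]], M = par[["M"]], tau = par[["tau"]],
    F_eq = par[["F_eq"]], C_eq = 1 - par[["F_eq"]],
    k_off = par[["k_off"]], F_inf = par[["F_inf"]],
    residence_time = 1 / par[["k_off"]],
    sse = best$sse, I0 = I0, plateau = plateau,
    variant = variant, n_frames = length(t),
    data = tibble(t = t, observed = y, fitted = fitted)
  ), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("FRAP reaction-diffusion fit (", x$variant, " series, ",
      x$n_frames, " frames)\n", sep = "")
  cat(sprintf("  K = %.4g  M = %.4g  tau = %.4g s\n", x$K, x$M, x$tau))
  cat(sprintf("  F_eq = %.4g  C_eq = %.4g  k_off = %.4g /s (residence %.3g s)\n",
              x$F_eq, x$C_eq, x$k_off, x$residence_time))
  cat(sprintf("  F_inf = %.4g  SSE = %.4g\n", x$F_inf, x$sse))
  invisible(x)
}

#' Tidy a FRAP fit
#'
#' @param x A `frap_fit` object.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(term = c("K", "M", "tau", "F_eq", "C_eq", "k_off", "F_inf"),
         estimate = c(x$K, x$M, x$tau, x$F_eq, x$C_eq, x$k_off, x$F_inf))
}

#' @rdname tidy.frap_fit
#' @return `glance()`: a one-row tibble with fit summaries.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(sse = x$sse, residence_time = x$residence_time, tau = x$tau,
         I0 = x$I0, plateau = x$plateau, n_frames = x$n_frames)
}

#' Plot a FRAP fit
#'
#' @param object A `frap_fit` object.
#' @param ... Unused.
#' @return A ggplot of the normalized recovery and the fitted curve.
#' @export
autoplot.frap_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$t)) +
    geom_point(aes(y = .data$observed), size = 0.4, alpha = 0.4) +
    geom_line(aes(y = .data$fitted), colour = "firebrick") +
    labs(x = "time after bleach (s)", y = "normalized intensity") +
    theme_minimal()
}
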