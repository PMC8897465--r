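#' FCS autocorrelation model with triplet state
#'
#' Multi-species 3D free-diffusion autocorrelation with a triplet-state
#' blinking factor and a long-lag offset:
#' \deqn{G(t) = 1 + \frac{1}{N}\Big(1 + \frac{T e^{-t/\tau_T}}{1-T}\Big)
#'   \sum_i \frac{f_i}{(1 + t/\tau_i)\sqrt{1 + t/(s^2 \tau_i)}} + G_\infty,}
#' where `N` is the mean number of molecules in the confocal volume, `T` the
#' triplet fraction with lifetime `tau_T`, `f_i` the fraction of species `i`
#' with diffusion time `tau_i = w_xy^2 / 4D`, and `s = w_z / w_xy` the
#' structure parameter of the detection volume.
#'
#' @param lags Lag times (s, > 0).
#' @param N Mean number of molecules (> 0).
#' @param T_trip Triplet fraction in `[0, 1)`.
#' @param tau_T Triplet lifetime (s).
#' @param f Species fractions (must sum to 1).
#' @param tau_d Species diffusion times (s, same length as `f`).
#' @param s_param Structure parameter `w_z / w_xy`.
#' @param G_inf Long-lag offset.
#' @return Numeric vector of `G` values.
#' @export
acf_model <- function(lags, N, T_trip = 0, tau_T = 1e-6, f = 1, tau_d,
                      s_param = 5, G_inf = 0) {
  if (N <= 0) stop_input("`N` must be > 0")
  if (T_trip >= 1 || T_trip < 0) stop_input("`T_trip` must be in [0, 1)")
  if (any(tau_d <= 0)) stop_input("diffusion times must be > 0")
  if (length(f) != length(tau_d)) stop_input("`f` and `tau_d` lengths differ")
  if (abs(sum(f) - 1) > 1e-8) stop_input("species fractions must sum to 1")
  triplet <- 1 + T_trip * exp(-lags / tau_T) / (1 - T_trip)
  diffusion <- 0
  for (i in seq_along(f)) {
    diffusion <- diffusion +
      f[[i]] / ((1 + lags / tau_d[[i]]) * sqrt(1 + lags / (s_param^2 * tau_d[[i]])))
  }
  1 + triplet * diffusion / N + G_inf
}

#' Fit the FCS autocorrelation model to a measured curve
#'
#' Bounded least squares of [acf_model()] with `n_species` diffusing
#' components (2 in the original analysis: a fast freely diffusing and a
#' slow chromatin-interacting population). The triplet lifetime is
#' constrained below 10 us, species fractions are parameterized on the
#' simplex (`f1` free in `[0, 1]` for two species), diffusion times are
#' reported sorted ascending, and the structure parameter is fixed (from
#' calibration, or the typical confocal value 5 by default). A deterministic
#' multi-start over diffusion-time decades guards against local minima.
#'
#' @param curve Tibble with columns `lag` (s) and `G`; optional `weight`.
#' @param n_species Number of diffusing species (1 or 2; default 2).
#' @param s_param Fixed structure parameter (default 5).
#' @param weights `"uniform"` (default) or `"inv_g2"` for 1/G^2 weighting.
#' @return Object of class `fcs_fit` with elements `N`, `T_trip`, `tau_T`,
#'   `f`, `tau_d`, `s_param`, `G_inf`, `sse` and a `data` tibble.
#' @export
fit_acf <- function(curve, n_species = 2, s_param = 5,
                    weights = c("uniform", "inv_g2")) {
  weights <- match.arg(weights)
  assert_cols(curve, c("lag", "G"), "ACF curve")
  if (any(curve$lag <= 0)) stop_input("lags must be > 0")
  lags <- curve$lag
  G <- curve$G
  wts <- if (weights == "inv_g2") 1 / G^2 else rep(1, length(G))
  amp <- max(G[which.min(lags)] - 1, 1e-3)
  N0 <- 1 / amp

  # diffusion times below the triplet window (10 us) are indistinguishable
  # from triplet blinking, so they are excluded from the diffusive component
  tau_floor <- max(1e-5, min(lags) / 10)
  if (n_species == 1) {
    par_names <- c("N", "T_trip", "tau_T", "tau1", "G_inf")
    lower <- c(N = 1e-4, T_trip = 0, tau_T = 1e-8, tau1 = tau_floor, G_inf = -0.5)
    upper <- c(N = 1e6, T_trip = 0.8, tau_T = 1e-5, tau1 = max(lags) * 10, G_inf = 0.5)
  } else if (n_species == 2) {
    par_names <- c("N", "T_trip", "tau_T", "f1", "tau1", "tau2", "G_inf")
    lower <- c(N = 1e-4, T_trip = 0, tau_T = 1e-8, f1 = 0,
               tau1 = tau_floor, tau2 = tau_floor, G_inf = -0.5)
    upper <- c(N = 1e6, T_trip = 0.8, tau_T = 1e-5, f1 = 1,
               tau1 = max(lags) * 10, tau2 = max(lags) * 10, G_inf = 0.5)
  } else {
    stop_input("`n_species` must be 1 or 2")
  }

  predict_from <- function(par) {
    if (n_species == 1) {
      acf_model(lags, N = par[["N"]], T_trip = par[["T_trip"]],
                tau_T = par[["tau_T"]], f = 1, tau_d = par[["tau1"]],
                s_param = s_param, G_inf = par[["G_inf"]])
    } else {
      acf_model(lags, N = par[["N"]], T_trip = par[["T_trip"]],
                tau_T = par[["tau_T"]], f = c(par[["f1"]], 1 - par[["f1"]]),
                tau_d = c(par[["tau1"]], par[["tau2"]]),
                s_param = s_param, G_inf = par[["G_inf"]])
    }
  }
  resid_fn <- function(par) sqrt(wts) * (predict_from(par) - G)

  qs <- quantile(lags, c(0.1, 0.35, 0.65, 0.9))
  starts <- list()
  tau_pairs <- if (n_species == 1) {
    list(qs[[2]], qs[[3]])
  } else {
    list(c(qs[[1]], qs[[3]]), c(qs[[1]], qs[[4]]), c(qs[[2]], qs[[4]]))
  }
  for (tp in tau_pairs) {
    for (f10 in if (n_species == 2) c(0.3, 0.7) else NA) {
      st <- c(N = N0, T_trip = 0.1, tau_T = 3e-6)
      if (n_species == 2) {
        st <- c(st, f1 = f10, tau1 = tp[[1]], tau2 = tp[[2]])
      } else {
        st <- c(st, tau1 = tp[[1]])
      }
      st <- c(st, G_inf = 0)
      starts[[length(starts) + 1L]] <- pmin(pmax(st[par_names], lower), upper)
    }
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    stop_fit("ACF fit failed to converge from every start",
             diagnostics = list(n_starts = length(starts)))
  }
  par <- coef(best$fit)
  if (n_species == 2) {
    f <- c(par[["f1"]], 1 - par[["f1"]])
    tau_d <- c(par[["tau1"]], par[["tau2"]])
    ord <- order(tau_d)
    f <- f[ord]
    tau_d <- tau_d[ord]
    # two components closer than a factor 2 in diffusion time are not
    # distinguishable at FCS noise levels: collapse to the mixture mean
    if (tau_d[[2]] / tau_d[[1]] < 2) {
      tau_w <- sum(f * tau_d)
      tau_d <- c(tau_w, tau_w)
      f <- c(1, 0)
    }
  } else {
    f <- 1
    tau_d <- par[["tau1"]]
  }
  structure(list(
    N = par[["N"]], T_trip = par[["T_trip"]], tau_T = par[["tau_T"]],
    f = f, tau_d = tau_d, s_param = s_param, G_inf = par[["G_inf"]],
    sse = best$sse, n_species = n_species,
    data = tibble(lag = lags, G = G, fitted = predict_from(par))
  ), class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("FCS fit (", x$n_species, " species, s = ", x$s_param, ")\n", sep = "")
  cat(sprintf("  N = %.4g  T = %.3g  tau_T = %.3g s  G_inf = %.3g\n",
              x$N, x$T_trip, x$tau_T, x$G_inf))
  for (i in seq_along(x$f)) {
    cat(sprintf("  species %d: f = %.3f  tau_d = %.4g s\n", i, x$f[[i]], x$tau_d[[i]]))
  }
  cat(sprintf("  SSE = %.4g\n", x$sse))
  invisible(x)
}

#' Tidy an FCS fit
#'
#' @param x An `fcs_fit` object.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @export
tidy.fcs_fit <- function(x, ...) {
  tibble(
    term = c("N", "T_trip", "tau_T", paste0("f", seq_along(x$f)),
             paste0("tau_d", seq_along(x$tau_d)), "G_inf"),
    estimate = c(x$N, x$T_trip, x$tau_T, x$f, x$tau_d, x$G_inf)
  )
}

#' @rdname tidy.fcs_fit
#' @export
glance.fcs_fit <- function(x, ...) {
  tibble(sse = x$sse, N = x$N, n_species = x$n_species,
         tau_fast = min(x$tau_d), tau_slow = max(x$tau_d))
}

#' Plot an FCS fit
#'
#' @param object An `fcs_fit` object.
#' @param ... Unused.
#' @return A ggplot of the ACF and fitted model on a log lag axis.
#' @export
autoplot.fcs_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$lag)) +
    geom_point(aes(y = .data$G), size = 0.6, alpha = 0.5) +
    geom_line(aes(y = .data$fitted), colour = "firebrick") +
    scale_x_log10() +
    labs(x = "lag (s)", y = "G(lag)") +
    theme_minimal()
}

#' Calibrate the confocal volume from a reference dye
#'
#' Given the fitted diffusion time of a calibrant of known diffusion
#' coefficient (Rhodamine 6G, `D = 414 um^2/s`, in the original
#' calibration), the lateral waist is `w_xy = sqrt(4 D tau)` and the axial
#' waist `w_z = s w_xy`.
#'
#' @param tau_cal Fitted diffusion time of the calibrant (s, > 0).
#' @param D_cal Known diffusion coefficient (um^2/s, default 414).
#' @param s_param Structure parameter (default 5).
#' @return One-row tibble with `w_xy`, `w_z`, `tau_cal`, `D_cal`, `s_param`.
#' @export
calibrate_volume <- function(tau_cal, D_cal = 414, s_param = 5) {
  if (tau_cal <= 0 || D_cal <= 0 || s_param <= 0) {
    stop_input("calibration inputs must be positive")
  }
  w_xy <- sqrt(4 * D_cal * tau_cal)
  tibble(w_xy = w_xy, w_z = s_param * w_xy, tau_cal = tau_cal,
         D_cal = D_cal, s_param = s_param)
}

#' Diffusion coefficient from an FCS diffusion time
#'
#' `D = w_xy^2 / (4 tau_d)`, the inverse of the calibration relation.
#'
#' @param tau_d Diffusion time (s, > 0).
#' @param w_xy Lateral confocal waist (um, > 0).
#' @return Diffusion coefficient in um^2/s.
#' @export
diffusion_from_tau <- function(tau_d, w_xy) {
  if (any(tau_d <= 0) || w_xy <= 0) stop_input("inputs must be positive")
  w_xy^2 / (4 * tau_d)
}
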