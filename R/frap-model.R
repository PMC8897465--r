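#' Correct and normalize a FRAP trace
#'
#' Double-normalization of a raw FRAP recovery: the bleached-ROI intensity is
#' first corrected by an unbleached neighbouring-nucleus ROI and an
#' extra-nuclear ROI,
#' \deqn{I_{corr}(t) = (I_{bl}(t) - I_{out}(t)) / (I_{unbl}(t) - I_{out}(t)),}
#' then divided by the mean pre-bleach value so the pre-bleach plateau sits
#' at 1. The denominator of the second step uses the *corrected* pre-bleach
#' values by default (`prebleach_mean = "corrected"`); the literal variant
#' dividing by the mean of the raw bleached-ROI intensities is available as
#' `prebleach_mean = "raw"`.
#'
#' @param trace Tibble with columns `time`, `i_bleach`, `i_unbleach`,
#'   `i_outside` (equal lengths, strictly increasing `time`).
#' @param n_prebleach Number of pre-bleach frames (default 10); the bleach is
#'   taken to occur between frames `n_prebleach` and `n_prebleach + 1`.
#' @param prebleach_mean `"corrected"` (default) or `"raw"`.
#' @return The trace tibble with added columns `i_corr` and `i_norm`.
#' @export
frap_normalize <- function(trace, n_prebleach = 10,
                           prebleach_mean = c("corrected", "raw")) {
  prebleach_mean <- match.arg(prebleach_mean)
  assert_cols(trace, c("time", "i_bleach", "i_unbleach", "i_outside"), "FRAP trace")
  if (n_prebleach >= nrow(trace)) {
    stop_input("`n_prebleach` must be smaller than the trace length")
  }
  if (any(diff(trace$time) <= 0)) stop_input("`time` must be strictly increasing")
  denom <- trace$i_unbleach - trace$i_outside
  if (any(denom == 0)) {
    abort("zero denominator (I_unbl == I_out) in ROI correction",
          class = "mitobook_correction_error")
  }
  i_corr <- (trace$i_bleach - trace$i_outside) / denom
  pre <- seq_len(n_prebleach)
  norm_by <- switch(prebleach_mean,
                    corrected = mean(i_corr[pre]),
                    raw = mean(trace$i_bleach[pre]))
  out <- mutate(as_tibble(trace), i_corr = i_corr, i_norm = i_corr / norm_by)
  attr(out, "n_prebleach") <- as.integer(n_prebleach)
  out
}

#' Reaction-diffusion FRAP recovery model
#'
#' Normalized fluorescence recovery of a factor that both diffuses and
#' exchanges on chromatin:
#' \deqn{F(t) = F_{eq} F_D(t) + C_{eq} F_{exc}(t), \quad C_{eq} = 1 - F_{eq},}
#' where the diffusive part is the order-20 truncation of the Axelrod
#' uniform-disk series adapted to Gaussian illumination,
#' \deqn{F_D(t) = \frac{1-e^{-K}}{K}(1-M) +
#'   M \sum_{n=1}^{20} \frac{(-K)^n}{n!} (1 + n + 2nt/\tau)^{-1},}
#' and the exchange part is
#' \deqn{F_{exc}(t) = F_\infty - ((1-e^{-K})/K - F_\infty) e^{-k_{off} t}.}
#' `K` is the bleach-depth constant, `M` the mobile fraction, `tau` the
#' characteristic diffusion time and `k_off` the chromatin unbinding rate
#' (residence time = `1/k_off`).
#'
#' The series as written starts at `n = 1`; with `variant =
#' "standard_axelrod"` the `n = 0` term is included inside the `M` sum (and
#' the `(1-M)` prefactor kept), which restores `F_D(0) = (1-e^{-K})/K` and
#' `F_D(\infty) = 1` for `M = 1`. Both forms are provided; the printed form
#' is the default.
#'
#' @param t Time since the first post-bleach frame (s), vector.
#' @param K Bleach-depth constant (> 0).
#' @param M Mobile fraction.
#' @param tau Characteristic diffusion recovery time (s, > 0).
#' @param F_eq Free (diffusing) equilibrium fraction in `[0, 1]`.
#' @param k_off Unbinding rate (1/s, > 0).
#' @param F_inf Asymptote of the exchange term.
#' @param variant `"literal"` (series from n = 1, default) or
#'   `"standard_axelrod"` (includes the n = 0 term).
#' @param n_terms Series truncation order (default 20).
#' @return Numeric vector of predicted normalized intensities.
#' @export
frap_model <- function(t, K, M = 1, tau, F_eq, k_off, F_inf = 1,
                       variant = c("literal", "standard_axelrod"),
                       n_terms = 20L) {
  variant <- match.arg(variant)
  if (K <= 0) stop_input("`K` must be > 0")
  if (tau <= 0) stop_input("`tau` must be > 0")
  F_eq * frap_fd(t, K, M, tau, variant, n_terms) +
    (1 - F_eq) * frap_fexc(t, K, k_off, F_inf)
}

frap_fd <- function(t, K, M, tau, variant = "literal", n_terms = 20L) {
  n0 <- if (variant == "standard_axelrod") 0L else 1L
  ns <- seq(n0, n_terms)
  coefs <- (-K)^ns / factorial(ns)
  terms <- outer(t, ns, function(tt, nn) 1 / (1 + nn + 2 * nn * tt / tau))
  (1 - exp(-K)) / K * (1 - M) + M * drop(terms %*% coefs)
}

frap_fexc <- function(t, K, k_off, F_inf) {
  F_inf - ((1 - exp(-K)) / K - F_inf) * exp(-k_off * t)
}

#' Build the bleach-depth correction table beta(K)
#'
#' For a pure-diffusion recovery, the half-recovery time depends on the
#' bleach depth `K` as well as on the characteristic time. For each `K` the
#' standard Axelrod recovery with characteristic time 1 is generated, its
#' half-recovery time (midpoint between `F(0)` and the plateau) is found
#' numerically, and `beta(K)` is that half-time. `beta` is monotone
#' increasing in `K`, and converts half-recovery times to diffusion
#' coefficients via [diffusion_coefficient()].
#'
#' @param K_grid Positive bleach-depth constants to tabulate (default a
#'   log-spaced grid over `[0.05, 20]`).
#' @param n_terms Series truncation order (default 50, higher than the model
#'   default so deep bleaches are accurately represented).
#' @return Tibble with columns `K` and `beta`.
#' @export
build_beta_table <- function(K_grid = exp(seq(log(0.05), log(20), length.out = 60)),
                             n_terms = 50L) {
  if (any(K_grid <= 0)) stop_input("`K_grid` must be positive")
  beta <- map_dbl(K_grid, frap_half_time, n_terms = n_terms)
  tibble(K = K_grid, beta = beta)
}

# Half-recovery time of the standard-Axelrod pure-diffusion curve with
# characteristic time 1 at bleach depth K.
frap_half_time <- function(K, n_terms = 50L) {
  f <- function(t) frap_fd(t, K, M = 1, tau = 1, variant = "standard_axelrod",
                           n_terms = n_terms)
  f0 <- f(0)
  plateau <- 1
  target <- (f0 + plateau) / 2
  uniroot(function(t) f(t) - target, lower = 1e-8, upper = 1e6,
          tol = 1e-10)$root
}

#' Diffusion coefficient from FRAP recovery time
#'
#' \deqn{D = \beta(K) w^2 / (4 \tau),} with `w` the 1/e^2 radius of the
#' Gaussian bleach beam (0.83 um for the original acquisitions) and
#' `beta(K)` the bleach-depth correction interpolated from a table built by
#' [build_beta_table()]. `tau` here is the measured half-recovery time; the
#' correction maps it back to the characteristic time scale.
#'
#' @param tau Half-recovery time (s, > 0).
#' @param K Bleach-depth constant at which to interpolate `beta`.
#' @param w Beam 1/e^2 radius in um (default 0.83).
#' @param beta_table Tibble from [build_beta_table()]; built on the fly if
#'   omitted.
#' @return Diffusion coefficient in um^2/s.
#' @export
diffusion_coefficient <- function(tau, K, w = 0.83, beta_table = NULL) {
  if (tau <= 0) stop_input("`tau` must be > 0")
  if (is.null(beta_table)) beta_table <- build_beta_table()
  if (K < min(beta_table$K) || K > max(beta_table$K)) {
    warn("K outside beta table range; extrapolating from nearest entries")
  }
  beta <- approx(beta_table$K, beta_table$beta, xout = K, rule = 2)$y
  beta * w^2 / (4 * tau)
}
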