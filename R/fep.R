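# Free-energy perturbation: per-window Zwanzig exponential averaging,
# autocorrelation-aware first-order error propagation, lambda-schedule
# construction/validation, thermodynamic-cycle assembly, and the Kd-ratio
# free-energy conversion.
#
# Per window, with beta = 1/(kB T):
#   dG_k  = -kB T log( (1/N) sum_i exp(-beta dU_i) )          (exponential
#           averaging over samples from the lambda_from ensemble)
#   sigma_k = kB T * sd(exp terms)/mean(exp terms) * sqrt((1+2 tau)/N)
#           (delta-method push of the ensemble-average error through the
#           logarithm; (1+2 tau) is the sampling ratio accounting for
#           autocorrelation)
# Totals assume independent windows: dG = sum dG_k, sigma^2 = sum sigma_k^2.

#' Construct one alchemical window
#'
#' @param delta_u ordered series of potential-energy differences
#'   `U(x; lambda_to) - U(x; lambda_from)` in kcal/mol, sampled from the
#'   `lambda_from` ensemble.
#' @param lambda_from,lambda_to coupling-parameter values in `[0, 1]`.
#' @param temperature K.
#' @return An object of class `pepmd_fep_window`.
#' @export
fep_window <- function(delta_u, lambda_from = 0, lambda_to = 1,
                       temperature = 300) {
  if (!length(delta_u)) stop("empty Delta-U series", call. = FALSE)
  if (!all(is.finite(delta_u)))
    stop("non-finite values in Delta-U series", call. = FALSE)
  stopifnot(lambda_from >= 0, lambda_from <= 1,
            lambda_to >= 0, lambda_to <= 1, temperature > 0)
  structure(list(delta_u = as.numeric(delta_u),
                 lambda_from = lambda_from, lambda_to = lambda_to,
                 temperature = temperature),
            class = "pepmd_fep_window")
}

#' Per-window free energy by exponential averaging
#'
#' `dG = -kB T log(mean(exp(-dU / kB T)))`, computed with a max-shifted
#' (log-sum-exp) formulation so large `|dU|` cannot overflow.
#'
#' @param win a [fep_window()].
#' @return Free-energy difference in kcal/mol.
#' @export
zwanzig_window_dg <- function(win) {
  stopifnot(inherits(win, "pepmd_fep_window"))
  kbt <- KB_KCAL * win$temperature
  x <- -win$delta_u / kbt
  m <- max(x)
  -kbt * (m + log(mean(exp(x - m))))
}

#' Statistical inefficiency of a sample series
#'
#' Estimates the correlation time tau (in sample steps) as the sum of
#' normalized autocovariances `C(t)/C(0)` from lag 1 up to the first lag at
#' which the normalized autocovariance drops below `cut` (default 0.05);
#' the sampling ratio is `1 + 2 tau` and the effective sample count
#' `N / (1 + 2 tau)`.
#'
#' @param series numeric vector (at least 50 samples).
#' @param cut truncation threshold on `C(t)/C(0)`.
#' @return A list: `tau`, `sampling_ratio`, `effective_n`, `degenerate`
#'   (TRUE for a zero-variance series, which returns ratio 1).
#' @export
statistical_inefficiency <- function(series, cut = 0.05) {
  n <- length(series)
  if (n < 50) stop("need at least 50 samples", call. = FALSE)
  if (var(series) <= .Machine$double.eps * max(1, mean(series)^2))
    return(list(tau = 0, sampling_ratio = 1, effective_n = n,
                degenerate = TRUE))
  # the truncation rule stops at the first lag with C(t)/C(0) < cut, so a
  # moderate lag window suffices; extended once if no lag falls below cut
  lag_max <- min(n - 1, 1000L)
  rho <- as.numeric(acf(series, lag.max = lag_max, plot = FALSE,
                        demean = TRUE)$acf)[-1]
  below <- which(rho < cut)
  if (!length(below) && lag_max < n - 1) {
    lag_max <- min(n - 1, 10000L)
    rho <- as.numeric(acf(series, lag.max = lag_max, plot = FALSE,
                          demean = TRUE)$acf)[-1]
    below <- which(rho < cut)
  }
  t_cut <- if (length(below)) below[1] - 1L else length(rho)
  tau <- if (t_cut >= 1) sum(rho[seq_len(t_cut)]) else 0
  tau <- max(tau, 0)
  list(tau = tau, sampling_ratio = 1 + 2 * tau,
       effective_n = n / (1 + 2 * tau), degenerate = FALSE)
}

#' First-order error of a window free energy
#'
#' Delta-method propagation of the statistical error of the exponential
#' ensemble average through the logarithm:
#' `sigma_k = kB T * sd(w)/mean(w) * sqrt((1 + 2 tau)/N)` where `w` are the
#' (max-shifted) exponential terms and `(1 + 2 tau)` the sampling ratio.
#'
#' @param win a [fep_window()].
#' @param ineff optional result of [statistical_inefficiency()]; computed
#'   from the exponential-term series when missing.
#' @return A list: `sigma` (kcal/mol), `ineff`, `low_effective_n` (TRUE
#'   when fewer than 10 effective samples back the estimate).
#' @export
window_error <- function(win, ineff = NULL) {
  stopifnot(inherits(win, "pepmd_fep_window"))
  kbt <- KB_KCAL * win$temperature
  x <- -win$delta_u / kbt
  m <- max(x)
  w <- exp(x - m)                       # shift cancels in sd/mean
  n <- length(w)
  if (sd(w) == 0)
    return(list(sigma = 0,
                ineff = list(tau = 0, sampling_ratio = 1,
                             effective_n = n, degenerate = TRUE),
                low_effective_n = n < 10))
  if (is.null(ineff)) {
    ineff <- if (n >= 50) statistical_inefficiency(w)
             else list(tau = 0, sampling_ratio = 1, effective_n = n,
                       degenerate = FALSE)
  }
  se_mean <- sd(w) * sqrt(ineff$sampling_ratio / n)
  list(sigma = kbt * se_mean / mean(w), ineff = ineff,
       low_effective_n = ineff$effective_n < 10)
}

#' Accumulate windows into a leg total
#'
#' Validates that the windows tile `[0, 1]` (each `lambda_to` equals the
#' next `lambda_from`; first 0, last 1), then sums free energies and adds
#' variances in quadrature (windows treated as independent observables).
#'
#' @param windows list of [fep_window()] in schedule order.
#' @param check_tiling validate the lambda schedule (default TRUE; disable
#'   for partial legs).
#' @return An object of class `pepmd_fep_result`: per-window table
#'   (`lambda_from`, `lambda_to`, `n`, `dg`, `sigma`, `sampling_ratio`),
#'   `dg`, `sigma`, `temperature`.
#' @export
accumulate <- function(windows, check_tiling = TRUE) {
  stopifnot(length(windows) >= 1)
  lf <- vapply(windows, function(w) w$lambda_from, numeric(1))
  lt <- vapply(windows, function(w) w$lambda_to, numeric(1))
  temps <- vapply(windows, function(w) w$temperature, numeric(1))
  if (length(unique(temps)) != 1)
    stop("windows have differing temperatures", call. = FALSE)
  if (check_tiling) {
    tol <- 1e-9
    if (abs(lf[1]) > tol)
      stop("lambda schedule does not start at 0 (starts at ", lf[1], ")",
           call. = FALSE)
    if (abs(lt[length(lt)] - 1) > tol)
      stop("lambda schedule does not end at 1 (ends at ",
           lt[length(lt)], ")", call. = FALSE)
    if (length(windows) > 1) {
      gaps <- which(abs(lt[-length(lt)] - lf[-1]) > tol)
      if (length(gaps))
        stop(sprintf(
          "gap/overlap in lambda tiling between windows %d and %d (%g vs %g)",
          gaps[1], gaps[1] + 1, lt[gaps[1]], lf[gaps[1] + 1]),
          call. = FALSE)
    }
  }
  dg <- vapply(windows, zwanzig_window_dg, numeric(1))
  errs <- lapply(windows, window_error)
  sg <- vapply(errs, function(e) e$sigma, numeric(1))
  ratio <- vapply(errs, function(e) e$ineff$sampling_ratio, numeric(1))
  tab <- data.frame(lambda_from = lf, lambda_to = lt,
                    n = vapply(windows, function(w) length(w$delta_u),
                               numeric(1)),
                    dg = dg, sigma = sg, sampling_ratio = ratio)
  structure(list(windows = tab, dg = sum(dg), sigma = sqrt(sum(sg^2)),
                 temperature = temps[1]),
            class = "pepmd_fep_result")
}

#' @export
print.pepmd_fep_result <- function(x, ...) {
  cat(sprintf("FEP leg: %d windows, dG = %.4f +/- %.4f kcal/mol (T = %g K)\n",
              nrow(x$windows), x$dg, x$sigma, x$temperature))
  invisible(x)
}

#' Lambda schedule with densified endpoints
#'
#' Breakpoints are the image of a uniform grid under the symmetric
#' regularized incomplete-beta warp `pbeta(u, a, a)` with
#' `a = endpoint_density`: `a = 1` recovers the uniform grid, `a > 1`
#' narrows the windows toward lambda = 0 and 1 (where alchemical
#' transformations are prone to singularities).
#'
#' @param n_windows number of windows (breakpoint count is
#'   `n_windows + 1`).
#' @param endpoint_density warp strength, `>= 1`.
#' @return Strictly increasing breakpoints from 0 to 1.
#' @export
lambda_schedule <- function(n_windows, endpoint_density = 1) {
  stopifnot(n_windows >= 1, endpoint_density >= 1)
  u <- seq(0, 1, length.out = n_windows + 1)
  lam <- pbeta(u, endpoint_density, endpoint_density)
  lam[1] <- 0; lam[n_windows + 1] <- 1
  lam
}

#' Thermodynamic-cycle binding free-energy difference
#'
#' Closes the alchemical cycle: `ddG_bind = dG(bound leg) - dG(free leg)`,
#' with errors combined in quadrature.  Both legs must share a temperature.
#'
#' @param bound_leg,free_leg `pepmd_fep_result` objects from
#'   [accumulate()].
#' @return A list: `ddg`, `sigma` (kcal/mol), `temperature`.
#' @export
cycle_ddg <- function(bound_leg, free_leg) {
  stopifnot(inherits(bound_leg, "pepmd_fep_result"),
            inherits(free_leg, "pepmd_fep_result"))
  if (abs(bound_leg$temperature - free_leg$temperature) > 1e-9)
    stop("cycle legs have different temperatures", call. = FALSE)
  list(ddg = bound_leg$dg - free_leg$dg,
       sigma = sqrt(bound_leg$sigma^2 + free_leg$sigma^2),
       temperature = bound_leg$temperature)
}

#' Binding free-energy difference from two dissociation constants
#'
#' `ddG = R T log(Kd_b / Kd_a)` with R = 1.987204e-3 kcal/(mol K); positive
#' when ligand b binds more weakly than ligand a.
#'
#' @param kd_a,kd_b dissociation constants in molar units.
#' @param temperature K (default 300).
#' @return ddG in kcal/mol.
#' @export
ddg_from_kd <- function(kd_a, kd_b, temperature = 300) {
  if (kd_a <= 0 || kd_b <= 0)
    stop("dissociation constants must be positive", call. = FALSE)
  stopifnot(temperature > 0)
  KB_KCAL * temperature * log(kd_b / kd_a)
}
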