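# Synthetic alchemical energy-difference windows: stationary AR(1) series
# with Gaussian marginals per lambda window.  For a Gaussian Delta-U with
# mean mu and sd sigma the exact Zwanzig free energy is known in closed
# form, mu - sigma^2 / (2 kB T), which makes the generated set a
# ground-truth fixture for the estimator and its error model.

#' Specification for synthetic FEP window samples
#'
#' @param mu per-window mean of Delta-U, kcal/mol (length = number of
#'   windows).
#' @param sigma per-window sd of Delta-U, kcal/mol (recycled).
#' @param ar1_phi lag-1 autocorrelation coefficient in `[0, 1)` (recycled).
#' @param n_samples samples per window (recycled).
#' @param temperature K.
#' @param seed integer RNG seed.
#' @param lambda optional vector of window breakpoints (length
#'   `n_windows + 1`, from 0 to 1); defaults to a uniform grid.
#' @return A `pepmd_fep_spec` with the exact total free energy
#'   `true_total_dg` attached.
#' @export
fep_synthetic_spec <- function(mu, sigma, ar1_phi = 0, n_samples = 1000,
                               temperature = 300, seed = 1L,
                               lambda = NULL) {
  k <- length(mu)
  sigma <- rep_len(sigma, k)
  ar1_phi <- rep_len(ar1_phi, k)
  n_samples <- rep_len(as.integer(n_samples), k)
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  if (any(ar1_phi < 0 | ar1_phi >= 1))
    stop("ar1_phi must lie in [0, 1)", call. = FALSE)
  stopifnot(temperature > 0, all(n_samples >= 1))
  if (is.null(lambda)) lambda <- seq(0, 1, length.out = k + 1)
  stopifnot(length(lambda) == k + 1, lambda[1] == 0, lambda[k + 1] == 1,
            all(diff(lambda) > 0))
  true_dg <- mu - sigma^2 / (2 * KB_KCAL * temperature)
  structure(list(mu = mu, sigma = sigma, ar1_phi = ar1_phi,
                 n_samples = n_samples, temperature = temperature,
                 seed = as.integer(seed), lambda = lambda,
                 true_window_dg = true_dg,
                 true_total_dg = sum(true_dg)),
            class = "pepmd_fep_spec")
}

#' Generate synthetic FEP windows
#'
#' Window k's Delta-U series is a stationary AR(1) process with marginal
#' Normal(mu_k, sigma_k^2) and lag-1 correlation `ar1_phi`: the first sample
#' is drawn from the stationary marginal and x_t = phi x_(t-1) + eps with
#' eps ~ N(0, sigma^2 (1 - phi^2)).  Reproducible from the seed.
#'
#' @param spec a [fep_synthetic_spec()].
#' @return A list: `windows` (list of [fep_window()]) and `true_total_dg`
#'   (kcal/mol).
#' @export
generate_fep_samples <- function(spec) {
  stopifnot(inherits(spec, "pepmd_fep_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  k <- length(spec$mu)
  windows <- vector("list", k)
  for (w in seq_len(k)) {
    n <- spec$n_samples[w]
    phi <- spec$ar1_phi[w]
    sg <- spec$sigma[w]
    if (sg == 0) {
      x <- rep(0, n)
    } else {
      x <- numeric(n)
      x[1] <- rnorm(1, 0, sg)
      if (n > 1) {
        innov <- rnorm(n - 1, 0, sg * sqrt(1 - phi^2))
        for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t - 1]
      }
    }
    windows[[w]] <- fep_window(delta_u = spec$mu[w] + x,
                               lambda_from = spec$lambda[w],
                               lambda_to = spec$lambda[w + 1],
                               temperature = spec$temperature)
  }
  list(windows = windows, true_total_dg = spec$true_total_dg,
       true_window_dg = spec$true_window_dg)
}

#' Write FEP windows as plain-text CSV files
#'
#' One CSV per window (columns `step`, `delta_u_kcal`) plus a YAML sidecar
#' (`lambda_from`, `lambda_to`, `temperature`, `discard`) per window, named
#' `window_<k>.csv` / `window_<k>.yaml` in `dir`.
#'
#' @param windows list of [fep_window()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of CSV paths.
#' @export
write_fep_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    csv <- file.path(dir, sprintf("window_%03d.csv", i))
    write.csv(data.frame(step = seq_along(w$delta_u),
                         delta_u_kcal = w$delta_u),
              csv, row.names = FALSE)
    yaml::write_yaml(list(lambda_from = w$lambda_from,
                          lambda_to = w$lambda_to,
                          temperature = w$temperature,
                          discard = 0L),
                     file.path(dir, sprintf("window_%03d.yaml", i)))
    paths[i] <- csv
  }
  invisible(paths)
}

#' Read FEP windows from a directory of CSV + YAML sidecars
#'
#' @param dir directory written by [write_fep_windows()] (or by any tool
#'   producing the same layout).
#' @return A list of [fep_window()], ordered by file name.
#' @export
read_fep_windows <- function(dir) {
  csvs <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(csvs)) stop("no window CSV files in ", dir, call. = FALSE)
  lapply(csvs, function(csv) {
    meta_path <- sub("\\.csv$", ".yaml", csv)
    if (!file.exists(meta_path))
      stop("missing YAML sidecar for ", csv, call. = FALSE)
    meta <- yaml::read_yaml(meta_path)
    tab <- read.csv(csv)
    du <- tab$delta_u_kcal
    discard <- if (is.null(meta$discard)) 0L else as.integer(meta$discard)
    if (discard > 0) du <- du[-seq_len(discard)]
    fep_window(du, meta$lambda_from, meta$lambda_to, meta$temperature)
  })
}
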