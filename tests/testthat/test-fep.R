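# Zwanzig exponential averaging, statistical inefficiency,
# autocorrelation-aware first-order errors, accumulation over a lambda
# schedule, the thermodynamic cycle, and the Kd conversion.

test_that("zwanzig estimator is exact for constant Delta-U", {
  w0 <- fep_window(rep(0, 100))
  expect_equal(zwanzig_window_dg(w0), 0)
  wc <- fep_window(rep(2.37, 100))
  expect_equal(zwanzig_window_dg(wc), 2.37)
  # numerically stable for huge energies (naive exp would overflow)
  whuge <- fep_window(rep(c(-5000, -4999), 50))
  expect_true(is.finite(zwanzig_window_dg(whuge)))
  expect_error(fep_window(numeric(0)), "empty")
  expect_error(fep_window(c(1, NA)), "non-finite")
})

test_that("zwanzig recovers the Gaussian closed form within 3 reported SE", {
  mu <- 1.0; sigma <- 0.5; temp <- 300
  truth <- mu - sigma^2 / (2 * kb_kcal() * temp)
  fs <- fep_synthetic_spec(mu = mu, sigma = sigma, n_samples = 1e6,
                           temperature = temp, seed = 20)
  w <- generate_fep_samples(fs)$windows[[1]]
  est <- zwanzig_window_dg(w)
  se <- window_error(w)$sigma
  expect_lt(abs(est - truth), 3 * se)
  expect_equal(est, 0.7903, tolerance = 0.005)
})

test_that("statistical inefficiency matches theory for white noise and AR(1)", {
  set.seed(21)
  white <- rnorm(1e5)
  si <- statistical_inefficiency(white)
  expect_gt(si$sampling_ratio, 0.9)
  expect_lt(si$sampling_ratio, 1.2)

  fs <- fep_synthetic_spec(mu = 0, sigma = 1, ar1_phi = 0.5,
                           n_samples = 1e5, seed = 22)
  x <- generate_fep_samples(fs)$windows[[1]]$delta_u
  si2 <- statistical_inefficiency(x)
  # AR(1) closed form: 1 + 2 sum phi^t = (1+phi)/(1-phi) = 3
  expect_lt(abs(si2$sampling_ratio - 3) / 3, 0.10)
  expect_lt(si2$effective_n, 1e5)

  const <- statistical_inefficiency(rep(1, 100))
  expect_true(const$degenerate)
  expect_equal(const$sampling_ratio, 1)
  expect_error(statistical_inefficiency(rnorm(10)), "at least 50")
})

test_that("window errors are calibrated, shrink as 1/sqrt(N), and grow with autocorrelation", {
  wconst <- fep_window(rep(1.5, 200))
  expect_equal(window_error(wconst)$sigma, 0)

  # doubling N shrinks sigma by sqrt(2) (iid)
  fs1 <- fep_synthetic_spec(mu = 0.5, sigma = 0.4, n_samples = 4e4, seed = 23)
  fs2 <- fep_synthetic_spec(mu = 0.5, sigma = 0.4, n_samples = 8e4, seed = 23)
  s1 <- window_error(generate_fep_samples(fs1)$windows[[1]])$sigma
  s2 <- window_error(generate_fep_samples(fs2)$windows[[1]])$sigma
  expect_equal(s1 / s2, sqrt(2), tolerance = 0.12)

  # autocorrelation inflates the reported error at fixed marginals
  f_iid <- fep_synthetic_spec(mu = 0, sigma = 0.5, ar1_phi = 0,
                              n_samples = 2e4, seed = 24)
  f_ac <- fep_synthetic_spec(mu = 0, sigma = 0.5, ar1_phi = 0.8,
                             n_samples = 2e4, seed = 24)
  s_iid <- window_error(generate_fep_samples(f_iid)$windows[[1]])$sigma
  s_ac <- window_error(generate_fep_samples(f_ac)$windows[[1]])$sigma
  expect_gt(s_ac, s_iid)

  # empirical coverage of +/- 1 sigma over 200 replicates in [0.55, 0.80]
  truth <- 0.8 - 0.5^2 / (2 * kb_kcal() * 300)
  hits <- vapply(1:200, function(s) {
    fs <- fep_synthetic_spec(mu = 0.8, sigma = 0.5, n_samples = 2000,
                             seed = 1000 + s)
    w <- generate_fep_samples(fs)$windows[[1]]
    abs(zwanzig_window_dg(w) - truth) <= window_error(w)$sigma
  }, logical(1))
  expect_gte(mean(hits), 0.55)
  expect_lte(mean(hits), 0.80)
})

test_that("accumulate validates the lambda tiling and totals in quadrature", {
  # hand-made two-window leg with known per-window results
  w1 <- fep_window(rep(1.0, 60), 0, 0.5)
  w2 <- fep_window(rep(2.0, 60), 0.5, 1)
  res <- accumulate(list(w1, w2))
  expect_equal(res$dg, 3.0)
  expect_equal(res$sigma, 0)

  single <- accumulate(list(fep_window(rep(0.7, 60), 0, 1)))
  expect_equal(single$dg, 0.7)

  # gap, overlap, and bad endpoints are schedule errors naming the break
  expect_error(accumulate(list(fep_window(1:60, 0, 0.4),
                               fep_window(1:60, 0.5, 1))),
               "windows 1 and 2")
  expect_error(accumulate(list(fep_window(1:60, 0.1, 1))), "start")
  expect_error(accumulate(list(fep_window(1:60, 0, 0.9))), "end")
  expect_error(accumulate(list(fep_window(1:60, 0, 1, temperature = 300),
                               fep_window(1:60, 0, 1, temperature = 310))),
               "temperatures")

  # synthetic 20-window schedule: total within 3 sigma of the known truth
  lam <- lambda_schedule(20, endpoint_density = 2)
  fs <- fep_synthetic_spec(mu = seq(-0.5, 0.5, length.out = 20),
                           sigma = 0.4, ar1_phi = 0.3, n_samples = 2000,
                           seed = 26, lambda = lam)
  gen <- generate_fep_samples(fs)
  res20 <- accumulate(gen$windows)
  expect_lt(abs(res20$dg - gen$true_total_dg), 3 * res20$sigma)

  # consistency: splitting one window's sample series into halves gives
  # two estimates of the same transformation whose mean agrees with the
  # full-series estimate within the combined statistical error
  fsA <- fep_synthetic_spec(mu = 0.3, sigma = 0.5, n_samples = 4000,
                            seed = 27)
  wA <- generate_fep_samples(fsA)$windows[[1]]
  half <- length(wA$delta_u) / 2
  wA1 <- fep_window(wA$delta_u[1:half], 0, 1)
  wA2 <- fep_window(wA$delta_u[(half + 1):length(wA$delta_u)], 0, 1)
  whole <- accumulate(list(wA))
  halves_mean <- mean(c(zwanzig_window_dg(wA1), zwanzig_window_dg(wA2)))
  comb <- sqrt(whole$sigma^2 +
               (window_error(wA1)$sigma^2 + window_error(wA2)$sigma^2) / 4)
  expect_lt(abs(whole$dg - halves_mean), 3 * comb)
})

test_that("lambda schedules densify toward the endpoints", {
  expect_equal(lambda_schedule(4, 1), c(0, 0.25, 0.5, 0.75, 1))
  for (n in c(5, 20, 69, 118)) {
    lam <- lambda_schedule(n, endpoint_density = 3)
    expect_equal(lam[1], 0)
    expect_equal(lam[n + 1], 1)
    expect_true(all(diff(lam) > 0))
    widths <- diff(lam)
    expect_lt(widths[1], widths[ceiling(n / 2)])
    expect_lt(widths[n], widths[ceiling(n / 2)])
    # a generated schedule is accepted by accumulate
    wins <- lapply(seq_len(n), function(k)
      fep_window(rep(0.01, 60), lam[k], lam[k + 1]))
    expect_equal(accumulate(wins)$dg, 0.01 * n)
  }
  expect_error(lambda_schedule(0), "n_windows")
})

test_that("thermodynamic cycle closes with quadrature-combined errors", {
  leg <- function(dg, sigma, temp = 300) {
    structure(list(windows = data.frame(), dg = dg, sigma = sigma,
                   temperature = temp), class = "pepmd_fep_result")
  }
  eq <- cycle_ddg(leg(5, 1), leg(5, 2))
  expect_equal(eq$ddg, 0)
  expect_equal(eq$sigma, sqrt(5))

  # combination rule on illustrative leg values: 10.0+/-2.0 minus
  # 1.4+/-6.4 gives 8.6+/-6.7
  cyc <- cycle_ddg(leg(10.0, 2.0), leg(1.4, 6.4))
  expect_equal(cyc$ddg, 8.6)
  expect_equal(cyc$sigma, 6.7, tolerance = 0.005)

  expect_error(cycle_ddg(leg(1, 1, 300), leg(1, 1, 310)), "temperatures")

  # synthetic legs with known truths: recovered difference within 3 sigma
  lam <- lambda_schedule(10, 2)
  fsb <- fep_synthetic_spec(mu = rep(0.4, 10), sigma = 0.4, n_samples = 2000,
                            seed = 28, lambda = lam)
  fsf <- fep_synthetic_spec(mu = rep(0.1, 10), sigma = 0.3, n_samples = 2000,
                            seed = 29, lambda = lam)
  gb <- generate_fep_samples(fsb); gf <- generate_fep_samples(fsf)
  cyc2 <- cycle_ddg(accumulate(gb$windows), accumulate(gf$windows))
  expect_lt(abs(cyc2$ddg - (gb$true_total_dg - gf$true_total_dg)),
            3 * cyc2$sigma)
})

test_that("Kd ratios convert to binding free-energy differences", {
  expect_equal(ddg_from_kd(5e-6, 5e-6, 300), 0)
  # RT = 0.6 kcal/mol at T = 0.6/R; ln(e) = 1
  t_rt06 <- 0.6 / kb_kcal()
  expect_equal(ddg_from_kd(1e-6, exp(1) * 1e-6, t_rt06), 0.6)
  # wild-type 7.2 uM vs phosphopeptide 100 uM at 300 K: 1.57 kcal/mol
  expect_equal(round(ddg_from_kd(7.2e-6, 100e-6, 300), 2), 1.57)
  expect_error(ddg_from_kd(0, 1e-6), "positive")
})
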