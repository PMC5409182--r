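stats_at <- function(mu, sigma = 4, tau = 15, tau0 = 32.3)
  list(mu_V = mu, sigma_V = sigma, tau_V = tau, tau_m0 = tau0)

test_that("threshold template: suppression, monotonicity, closed form", {
  p <- firing_response_params(V0 = -48)
  # 10 sigma below threshold: essentially silent
  expect_lt(firing_rate(p, stats_at(-48 - 10 * 4)), 1e-5)
  # monotone increasing in mu_V
  mus <- seq(-70, -40, by = 2)
  nus <- vapply(mus, function(m) firing_rate(p, stats_at(m)), numeric(1))
  expect_true(all(diff(nus) >= 0))
  # at threshold the template gives exactly 1/(2 tau_V)
  expect_equal(firing_rate(p, stats_at(-48)), 1 / (2 * 15e-3),
               tolerance = 1e-12)
  expect_true(all(nus >= 0))
})

test_that("characterization separates excitability from sensitivities", {
  p0 <- firing_response_params(V0 = -50)
  p1 <- firing_response_params(V0 = -44)   # less excitable, same shape
  c0 <- characterize_response(p0)
  c1 <- characterize_response(p1)
  expect_equal(c1$excitability - c0$excitability, 6, tolerance = 1e-10)
  expect_equal(c0$sens_mu, c1$sens_mu)
  expect_equal(c0$sens_sigma, c1$sens_sigma)
  expect_equal(c0$sens_tau, c1$sens_tau)
  expect_gt(c0$sens_mu, 0)
  expect_error(characterize_response(p0, domain = list(mu = c(-60, -60),
                                                       sigma = c(1, 7),
                                                       tau = c(0.1, 1))),
               "degenerate")
})

test_that("analytic sensitivities match finite differences", {
  p <- firing_response_params(V0 = -50, a_mu = 0.2, a_sigma = -0.3,
                              a_tau = 2)
  tau0 <- 32.3
  base <- stats_at(-55, 4, 0.5 * tau0, tau0)
  h <- 1e-5
  fd <- function(field, hh) {
    up <- base; up[[field]] <- up[[field]] + hh
    (firing_rate(p, up) - firing_rate(p, base)) / hh
  }
  d_mu <- fd("mu_V", h)
  d_sigma <- fd("sigma_V", h)
  d_tauV <- fd("tau_V", h * tau0) * tau0   # per unit tau_VN
  # analytic forms (the template's closed-form partials)
  vth <- -50 + 0.2 * (-55 + 60) + (-0.3) * (4 - 4) + 2 * (0.5 - 0.5)
  u <- (-55 - vth) / 4
  tau_s <- 0.5 * tau0 * 1e-3
  expect_equal(d_mu, stats::dnorm(u) * (1 - 0.2) / 4 / tau_s,
               tolerance = 1e-3)
  expect_equal(d_sigma, stats::dnorm(u) * (0.3 - u) / 4 / tau_s,
               tolerance = 1e-3)
  expect_equal(d_tauV,
               -stats::pnorm(u) / tau_s / 0.5 +
                 stats::dnorm(u) * (-2 / 4) / tau_s,
               tolerance = 1e-3)
})

test_that("composition consistency of the transfer function", {
  tree <- med_tree(); pas <- med_passive(); syn <- med_syn()
  p <- firing_response_params(V0 = -50)
  F <- transfer_function(tree, pas, syn, p)
  st <- baseline_state()
  fs <- baseline_analytic()
  expect_equal(F(st), firing_rate(p, fs), tolerance = 1e-9)
  # high- vs low-excitability cells differ by orders of magnitude
  lo <- firing_rate(firing_response_params(V0 = -40), fs)
  hi <- firing_rate(firing_response_params(V0 = -52), fs)
  expect_gt(hi / max(lo, 1e-30), 100)
})

test_that("synthetic populations are reproducible and normally excitable", {
  pop1 <- synthesize_population(30, seed = 2)
  pop2 <- synthesize_population(30, seed = 2)
  expect_identical(pop1, pop2)
  big <- synthesize_population(1000, seed = 5)
  V0 <- vapply(big, `[[`, numeric(1), "V0")
  expect_gt(stats::shapiro.test(V0)$p.value, 0.01)
  R_in <- vapply(big, attr, numeric(1), "R_in")
  expect_true(all(R_in >= 280 & R_in <= 850))
})

test_that("population couplings reproduce the qualitative structure", {
  pc <- cached("pop_couplings",
               population_couplings(synthesize_population(20, seed = 1),
                                    n_steps = 3))
  per <- pc$per_cell
  keep <- !(per$id %in% pc$excluded)
  # baseline rates: strong link to excitability on the log scale
  ct <- stats::cor.test(log10(per$nu_bsl[keep]), per$excitability[keep])
  expect_lt(ct$estimate, -0.8)
  expect_lt(ct$p.value, 0.01)
  # unbalanced and synchrony responses are positive increases
  expect_true(all(per$dnu_ubl[keep] > 0))
  expect_true(all(per$dnu_synch[keep] > 0))
  # proximal responses show sign heterogeneity
  expect_true(any(per$dnu_prox[keep] > 0) && any(per$dnu_prox[keep] < 0))
  expect_error(population_couplings(synthesize_population(1, seed = 1)),
               "two cells")
  # determinism of the full coupling analysis
  pc2 <- population_couplings(synthesize_population(20, seed = 1),
                              n_steps = 3)
  expect_identical(pc$per_cell, pc2$per_cell)
})
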