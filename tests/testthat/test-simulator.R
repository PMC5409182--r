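test_that("discretization: counts, areas and topology", {
  cell <- discretize(med_tree(), med_passive(), med_syn(), nseg = 30)
  expect_equal(cell$n_comp, 31 * 30 + 1)   # 2^5 - 1 branches x nseg + soma
  expect_equal(sum(cell$comp$area[-1]) * 1e12,
               membrane_areas(med_tree())$tree_total, tolerance = 1e-3)
  # parent ordering supports the tree solve
  expect_true(all(cell$comp$parent[-1] < seq_len(cell$n_comp)[-1]))
  # total synapse budget matches the closed-form counts
  sc <- synapse_counts(med_tree(), med_syn())
  expect_equal(sum(cell$n_e[-1]), sc$Ne_tree, tolerance = 1e-6)
  expect_equal(sum(cell$n_i[-1]), sc$Ni_tree, tolerance = 1e-6)
  expect_equal(cell$n_i[1], sc$Ni_soma, tolerance = 1e-6)
  # zero-density type contributes no events
  syn0 <- synaptic_params(De_tree = 0)
  cell0 <- discretize(med_tree(), med_passive(), syn0, nseg = 5)
  expect_equal(sum(cell0$n_e), 0)
})

test_that("quiescent and single-event behaviour", {
  cell <- discretize(med_tree(), med_passive(), med_syn(), nseg = 10)
  r0 <- simulate_cell(cell, NULL, T_ms = 100, dt_ms = 0.05)
  expect_equal(r0$v_soma, rep(-65, length(r0$v_soma)), tolerance = 1e-9)
  # one excitatory event: positive transient returning towards rest
  r1 <- simulate_cell(cell, NULL, T_ms = 300, dt_ms = 0.05,
                      events = data.frame(time_ms = 50, x_um = 100,
                                          type = "e", q_nS = 0.7))
  expect_gt(max(r1$v_soma), -65 + 0.5)
  expect_lt(abs(r1$v_soma[length(r1$v_soma)] + 65), 0.05)
  # passive linearity: at small quantal, doubling Q doubles the peak
  peak_of <- function(q) {
    r <- simulate_cell(cell, NULL, T_ms = 200, dt_ms = 0.05,
                       events = data.frame(time_ms = 20, x_um = 100,
                                           type = "e", q_nS = q))
    max(r$v_soma) + 65
  }
  expect_equal(peak_of(0.02) / peak_of(0.01), 2, tolerance = 0.01)
})

test_that("integration is deterministic and convergent", {
  cell <- discretize(med_tree(), med_passive(), med_syn(), nseg = 30)
  st <- baseline_state()
  a <- simulate_cell(cell, st, T_ms = 300, dt_ms = 0.05, seed = 3)
  b <- simulate_cell(cell, st, T_ms = 300, dt_ms = 0.05, seed = 3)
  expect_identical(a$v_soma, b$v_soma)
  # halving dt / doubling nseg barely moves the measured statistics
  m1 <- measure_stats(simulate_cell(cell, st, 1000, 0.05, seed = 1)$v_soma,
                      0.05)
  m2 <- measure_stats(simulate_cell(cell, st, 1000, 0.025, seed = 1)$v_soma,
                      0.025)
  expect_lt(abs(m2$mu_V - m1$mu_V) / abs(m1$mu_V), 0.01)
  expect_lt(abs(m2$sigma_V - m1$sigma_V) / m1$sigma_V, 0.05)
  # spatial convergence, checked deterministically: a single PSP and the
  # settled mean under static background move by < 1% from nseg 30 to 60
  cell60 <- discretize(med_tree(), med_passive(), med_syn(), nseg = 60)
  psp_peak <- function(cl) {
    r <- simulate_cell(cl, NULL, T_ms = 400, dt_ms = 0.05,
                       mean_background = st,
                       events = data.frame(time_ms = 300, x_um = 400,
                                           type = "e", q_nS = 0.7))
    max(r$v_soma[r$t_ms >= 299.99]) - r$v_soma[which.min(abs(r$t_ms - 299.95))]
  }
  expect_lt(abs(psp_peak(cell60) - psp_peak(cell)) / psp_peak(cell), 0.01)
})

test_that("voltage stays within the physical reversal bounds", {
  cell <- discretize(med_tree(), med_passive(), med_syn(), nseg = 30)
  r <- simulate_cell(cell, baseline_state(), T_ms = 500, dt_ms = 0.05,
                     seed = 2, probes_x = c(250, 540))
  expect_true(all(r$v_soma > -85 & r$v_soma < 5))
  expect_true(all(r$v_probe > -85 & r$v_probe < 5))
})

test_that("measure_stats recovers known OU statistics", {
  x <- ou_trace(20000, 0.5, mu = -60, sigma = 4, tau_ms = 20, seed = 4)
  m <- measure_stats(x, 0.5, t_discard_ms = 500)
  expect_equal(m$mu_V, -60, tolerance = 0.01)
  expect_equal(m$sigma_V, 4, tolerance = 0.05)
  expect_equal(m$tau_V, 20, tolerance = 0.1 * 20)
  m0 <- measure_stats(rep(-65, 5000), 0.5)
  expect_equal(m0$sigma_V, 0)
  # seed-to-seed scatter of sigma_V at the baseline is small
  ss <- baseline_simulated()
  expect_lt(ss$sd_sigma, 0.6)
})
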