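test_that("resting reduction reproduces the tree's input resistance", {
  tree <- med_tree(); pas <- med_passive()
  cyl <- reduce_to_cylinder(tree, pas)
  # the reduced cable preserves the somatic input admittance by construction;
  # cross-check against the impedance route
  R_cyl <- input_resistance(tree, pas)
  expect_lt(abs(Re(model_input_impedance(tree, pas, 0)) - R_cyl) / R_cyl,
            1e-9)
  expect_true(all(cyl$segments$tau_eff > 0))
  expect_gt(cyl$L_prox, 0)
  expect_gt(cyl$L_dist, 0)
})

test_that("mean bombardment shortens space and time constants", {
  tree <- med_tree(); pas <- med_passive(); syn <- med_syn()
  rest <- reduce_to_cylinder(tree, pas, syn, NULL)
  base <- reduce_to_cylinder(tree, pas, syn, baseline_state())
  expect_true(all(base$segments$tau_eff < rest$segments$tau_eff))
  expect_true(all(base$segments$lambda < rest$segments$lambda))
  # stronger proximal drive shrinks proximal constants further
  prox <- reduce_to_cylinder(tree, pas, syn,
                             presynaptic_state(nu_ep = 1.7, nu_ip = 8))
  ip <- base$segments$domain == "proximal"
  expect_true(all(prox$segments$lambda[ip] < base$segments$lambda[ip]))
})

test_that("stationary profile: rest limit and reversal bounds", {
  tree <- med_tree(); pas <- med_passive(); syn <- med_syn()
  mp0 <- stationary_mean_profile(presynaptic_state(0, 0, 0, 0, 0),
                                 tree, pas, syn)
  expect_equal(mp0$mu, rep(-65, length(mp0$mu)), tolerance = 1e-9)
  mp <- stationary_mean_profile(baseline_state(), tree, pas, syn)
  expect_true(all(mp$mu > -80 & mp$mu < 0))
  # the balanced baseline sits in the -55 mV neighbourhood at the soma
  expect_lt(abs(mp$mu_soma - -55), 3)
  # simulator cross-check of the somatic mean (4 seeds)
  ss <- baseline_simulated()
  expect_lt(abs(ss$mu_V - mp$mu_soma), 1)
})

test_that("PSP kernels: nullity, filtering and simulator cross-check", {
  tree <- med_tree(); pas <- med_passive(); syn <- med_syn()
  st <- baseline_state()
  cyl <- reduce_to_cylinder(tree, pas, syn, st)
  # zero quantal -> identically zero kernel
  syn0 <- med_syn(); syn0$Qep <- 0
  cyl0 <- reduce_to_cylinder(tree, pas, syn0, st)
  k0 <- psp_kernel(cyl0, 100, "e", f = c(0, 10, 100))
  expect_equal(Mod(k0$ft), rep(0, 3))
  # distal events are more low-pass filtered than proximal ones
  kp <- psp_kernel(cyl, 100, "e", f = c(0, 100))
  kd <- psp_kernel(cyl, 540, "e", f = c(0, 100))
  expect_lt(Mod(kd$ft[2]) / Mod(kd$ft[1]), Mod(kp$ft[2]) / Mod(kp$ft[1]))
  # amplitude decreases with distance within a domain (equal quantal)
  dc <- vapply(c(20, 150, 300, 450), function(x)
    Mod(psp_kernel(cyl, x, "e", f = 0)$ft), numeric(1))
  expect_true(all(diff(dc) < 0))
  # excitatory kernel is positive, inhibitory negative
  expect_gt(kp$drive, 0)
  expect_lt(psp_kernel(cyl, 100, "i", f = 0)$drive, 0)
  expect_error(psp_kernel(cyl, 1000, "e"), "outside")
  expect_error(psp_kernel(cyl, 0, "e"), "inhibitory")
  # single-event somatic PSP from the simulator (quiescent cell carrying
  # the baseline mean conductances) within 30% of the kernel peak
  cell <- discretize(tree, pas, syn, nseg = 30)
  peak_ana <- max(kp$time_course(seq(0, 120, 0.5)))
  r <- simulate_cell(cell, NULL, T_ms = 600, dt_ms = 0.05,
                     mean_background = st,
                     events = data.frame(time_ms = 400, x_um = 100,
                                         type = "e", q_nS = syn$Qep))
  settled <- r$v_soma[which.min(abs(r$t_ms - 399.95))]
  peak_sim <- max(r$v_soma[r$t_ms >= 399.99]) - settled
  expect_lt(abs(peak_ana - peak_sim) / peak_sim, 0.30)
})

test_that("fluctuation statistics: degenerate input and synchrony sweep", {
  tree <- med_tree(); pas <- med_passive(); syn <- med_syn()
  fs0 <- fluctuation_stats(presynaptic_state(0, 0, 0, 0, 0),
                           tree, pas, syn)
  expect_equal(fs0$sigma_V, 0)
  expect_equal(fs0$mu_V, -65)
  expect_equal(fs0$g_ratio, 1)
  s_seq <- c(0.05, 0.15, 0.25, 0.4)
  out <- lapply(s_seq, function(si)
    fluctuation_stats(presynaptic_state(s = si), tree, pas, syn))
  mu <- vapply(out, `[[`, numeric(1), "mu_V")
  sg <- vapply(out, `[[`, numeric(1), "sigma_V")
  tv <- vapply(out, `[[`, numeric(1), "tau_V")
  expect_lt(diff(range(mu)) / abs(mean(mu)), 0.01)
  expect_lt(diff(range(tv)) / mean(tv), 0.01)
  expect_true(all(diff(sg) > 0))
  # near-linear growth of sigma_V with s
  fit <- stats::lm(sg ~ s_seq)
  expect_gt(summary(fit)$r.squared, 0.98)
})

test_that("variance is homogeneous of degree one in the rates (weak drive)", {
  tree <- med_tree(); pas <- med_passive(); syn <- med_syn()
  st1 <- presynaptic_state(2e-4, 1.2e-3, 2e-4, 1.2e-3, 0)
  st2 <- presynaptic_state(4e-4, 2.4e-3, 4e-4, 2.4e-3, 0)
  v1 <- fluctuation_stats(st1, tree, pas, syn)$sigma_V^2
  v2 <- fluctuation_stats(st2, tree, pas, syn)$sigma_V^2
  expect_equal(v2 / v1, 2, tolerance = 0.01)
})

test_that("position and frequency quadrature are converged", {
  tree <- med_tree(); pas <- med_passive(); syn <- med_syn()
  st <- baseline_state()
  a <- fluctuation_stats(st, tree, pas, syn, nodes_per_seg = 16)
  b <- fluctuation_stats(st, tree, pas, syn, nodes_per_seg = 32)
  expect_equal(a$sigma_V, b$sigma_V, tolerance = 1e-6)
  expect_equal(a$tau_V, b$tau_V, tolerance = 1e-6)
  fine <- c(0, 10^seq(-2, 4, length.out = 481))
  cc <- fluctuation_stats(st, tree, pas, syn, f = fine)
  expect_equal(a$sigma_V, cc$sigma_V, tolerance = 1e-3)
})

test_that("conductance ratio: unity at rest, grows under the protocols", {
  tree <- med_tree(); pas <- med_passive(); syn <- med_syn()
  expect_equal(conductance_ratio(presynaptic_state(0, 0, 0, 0, 0),
                                 tree, pas, syn), 1, tolerance = 1e-9)
  g_base <- conductance_ratio(baseline_state(), tree, pas, syn)
  expect_gt(g_base, 1)
  g_prox <- conductance_ratio(presynaptic_state(nu_ep = 1.7, nu_ip = 11.6),
                              tree, pas, syn)
  expect_gt(g_prox, 2 * g_base)
})
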