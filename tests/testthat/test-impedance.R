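test_that("RC impedance has the textbook limits", {
  RM <- 200; CM <- 0.1  # MOhm, nF -> tau = 20 ms
  expect_equal(Mod(rc_impedance(RM, CM, 1e-6)), RM, tolerance = 1e-6)
  expect_equal(-Arg(rc_impedance(RM, CM, 1e-6)), 0, tolerance = 1e-3)
  # corner frequency: phase lag pi/4
  fc <- 1 / (2 * pi * RM * CM * 1e-3)
  expect_equal(-Arg(rc_impedance(RM, CM, fc)), pi / 4, tolerance = 1e-10)
  # -1 log-log modulus slope at high frequency
  f <- c(2e3, 2e4)
  slope <- diff(log(Mod(rc_impedance(RM, CM, f)))) / diff(log(f))
  expect_equal(slope, -1, tolerance = 1e-3)
})

test_that("model impedance: DC equals input resistance, vanishing tree -> soma RC", {
  tree <- med_tree(); pas <- med_passive()
  expect_equal(Re(model_input_impedance(tree, pas, 0)),
               input_resistance(tree, pas), tolerance = 1e-9)
  # dt -> 0: the tree admittance vanishes and the soma RC remains
  thin <- build_tree(dt = 1e-4)
  f <- c(0.5, 5, 50)
  A_s <- pi * 15 * 5 * 1e-8          # cm^2
  RM <- 1 / (pas$GL * 1e-6 * A_s) / 1e6   # MOhm
  CM <- pas$Cm * 1e-3 * A_s * 1e6         # nF
  expect_equal(Mod(model_input_impedance(thin, pas, f)),
               Mod(rc_impedance(RM, CM, f)), tolerance = 1e-3)
})

test_that("dendritic tree bends modulus slope and phase away from the RC case", {
  tree <- med_tree(); pas <- med_passive()
  f <- c(500, 5000)
  slope <- diff(log(Mod(model_input_impedance(tree, pas, f)))) / diff(log(f))
  expect_gt(slope, -1)   # shallower than the single-compartment exponent
  expect_lt(slope, -0.5)
  # phase lag bounded above by the lumped-RC phase over 10-200 Hz
  R <- input_resistance(tree, pas)
  Ctot_nF <- pas$Cm * 1e-3 *
    (membrane_areas(tree)$tree_total + membrane_areas(tree)$soma) * 1e-8 * 1e6
  ff <- c(10, 20, 50, 100, 150, 200)
  expect_true(all(-Arg(model_input_impedance(tree, pas, ff)) <
                    -Arg(rc_impedance(R, Ctot_nF, ff))))
})

test_that("model impedance agrees with the compartmental simulator", {
  tree <- med_tree(); pas <- med_passive(); syn <- med_syn()
  cell <- discretize(tree, pas, syn, nseg = 30)
  for (f in c(1, 10, 100)) {
    T_ms <- max(5 / f * 1e3, 400)
    r <- simulate_cell(cell, NULL, T_ms = T_ms, dt_ms = 0.05,
                       I_amp_nA = 0.005, I_freq_Hz = f)
    sf <- fit_sine_response(r$t_ms, r$v_soma, 0.005, f)
    Z <- model_input_impedance(tree, pas, f)
    expect_equal(sf$R_est, Mod(Z), tolerance = 0.02)
    expect_equal(sf$phi_est, -Arg(Z), tolerance = 0.02 * max(1, -Arg(Z)))
  }
})

test_that("sine fit recovers generative parameters", {
  t_ms <- seq(0, 2000, by = 0.5)
  f <- 10; I <- 0.01; R <- 150; phi <- 0.6; EL <- -65
  v <- EL + R * I * sin(2 * pi * f * t_ms * 1e-3 - phi)
  fit <- fit_sine_response(t_ms, v, I, f)
  expect_equal(fit$EL_est, EL, tolerance = 1e-8)
  expect_equal(fit$R_est, R, tolerance = 1e-8)
  expect_equal(fit$phi_est, phi, tolerance = 1e-8)
  expect_lt(fit$residual, 1e-8)
  # white noise: recovery within 3 standard errors
  set.seed(42)
  vn <- v + rnorm(length(v), 0, 0.1)
  fitn <- fit_sine_response(t_ms, vn, I, f)
  se_RI <- 0.1 * sqrt(2 / sum(t_ms * 1e-3 >= 3 / f))
  expect_lt(abs(fitn$R_est - R), 3 * se_RI / I)
  # frequency mismatch inflates the residual far above the noise floor
  fitm <- fit_sine_response(t_ms, vn, I, f * 1.1)
  expect_gt(fitm$residual, 3 * fitn$residual)
  # too-short trace (under n_discard + 1 periods) is rejected
  tt <- seq(0, 350, 0.5)
  expect_error(fit_sine_response(tt, v[seq_along(tt)], I, 10), "periods")
})

test_that("grid fit exactly recovers on-grid models and is deterministic", {
  grid <- shared_impedance_grid()
  set.seed(7)
  idx <- sample.int(nrow(grid$params), 20)
  hits <- vapply(idx, function(i) {
    sp <- list(f = grid$f, modulus = grid$modulus[i, ],
               phase = grid$phase[i, ])
    grid_fit_mean_model(sp, grid)$index == i
  }, logical(1))
  expect_true(all(hits))
  sp <- list(f = grid$f, modulus = grid$modulus[idx[1], ],
             phase = grid$phase[idx[1], ])
  expect_identical(grid_fit_mean_model(sp, grid)$index,
                   grid_fit_mean_model(sp, grid)$index)
  expect_error(grid_fit_mean_model(list(f = 1, modulus = 2, phase = 0),
                                   grid), "degenerate|match")
})

test_that("impedance table round trip preserves the spectrum", {
  grid <- shared_impedance_grid()
  sp <- list(f = grid$f, modulus = grid$modulus[100, ],
             phase = grid$phase[100, ])
  path <- tempfile(fileext = ".tsv")
  write_impedance_table(sp, path)
  back <- read_impedance_table(path)
  expect_equal(back$modulus, sp$modulus, tolerance = 1e-6)
  expect_equal(back$phase, sp$phase, tolerance = 1e-6)
})
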