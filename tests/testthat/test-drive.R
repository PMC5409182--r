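test_that("multiplicity moments follow the coincidence algebra", {
  m0 <- multiplicity_moments(0)
  expect_equal(m0$Em, 1)
  expect_equal(m0$Em2, 1)
  expect_equal(m0$probs, c(1, 0, 0, 0))
  m4 <- multiplicity_moments(0.4)
  expect_equal(m4$Em, 1.624)                 # 1 + s + s^2 + s^3
  expect_equal(m4$probs[4], 0.064)           # quadruple probability s^3
  expect_equal(sum(m4$probs), 1)
  # E[m] and E[m^2] agree with the direct expectation over the pmf
  for (s in c(0.1, 0.25, 0.4)) {
    mm <- multiplicity_moments(s)
    expect_equal(mm$Em, sum((1:4) * mm$probs), tolerance = 1e-12)
    expect_equal(mm$Em2, sum((1:4)^2 * mm$probs), tolerance = 1e-12)
    # generator rate x E[m] returns the nominal rate
    expect_equal((1 / mm$Em) * mm$Em, 1)
  }
})

test_that("synchrony trains conserve the event rate and multiplicity law", {
  # generator frequency at nu = 1.2 Hz, s = 0.05
  expect_equal(1.2 / multiplicity_moments(0.05)$Em, 1.1400,
               tolerance = 1e-4)
  for (s in c(0, 0.1, 0.25, 0.4)) {
    nu <- 40; T_ms <- 50000
    tr <- synchrony_train(nu, s, T_ms, seed = 100 + round(100 * s))
    n <- length(tr)
    expected <- nu * T_ms / 1000
    expect_lt(abs(n - expected) / sqrt(expected *
                                         multiplicity_moments(s)$Em2 /
                                         multiplicity_moments(s)$Em), 4)
    expect_true(!is.unsorted(tr))
    expect_true(all(tr >= 0 & tr <= T_ms))
  }
  # s = 0 is a plain Poisson process: no duplicated timestamps
  tr0 <- synchrony_train(50, 0, 20000, seed = 11)
  expect_equal(anyDuplicated(tr0), 0)
  # multiplicity histogram matches the stated probabilities (chi-square)
  s <- 0.25
  tr <- synchrony_train(2000, s, 50000, seed = 5)
  m <- attr(tr, "multiplicities")
  obs <- tabulate(m, nbins = 4)
  expect_gt(stats::chisq.test(obs, p = multiplicity_moments(s)$probs)$p.value,
            0.01)
  expect_error(synchrony_train(1, 1, 1000), "s must lie")
  expect_warning(synchrony_train(1, 0.5, 1000, seed = 1), "0.4")
})

test_that("distinct synapse substreams are independent", {
  t1 <- synchrony_train(200, 0.2, 20000, seed = 1)
  t2 <- synchrony_train(200, 0.2, 20000, seed = 2)
  # zero-lag coincidences (1 ms bins) consistent with chance
  b1 <- tabulate(floor(t1) + 1, nbins = 20000)
  b2 <- tabulate(floor(t2) + 1, nbins = 20000)
  r <- suppressWarnings(cor(b1, b2))
  expect_lt(abs(r), 3 / sqrt(20000))
  # reproducibility contract
  expect_identical(as.numeric(synchrony_train(200, 0.2, 1000, seed = 9)),
                   as.numeric(synchrony_train(200, 0.2, 1000, seed = 9)))
})

test_that("mean conductance fields are linear in the rates and piecewise", {
  tree <- med_tree(); syn <- med_syn()
  z <- mean_conductance_densities(
    presynaptic_state(0, 0, 0, 0, 0), tree, syn)
  expect_equal(z$areal$ge, c(0, 0))
  expect_equal(z$soma_Gi, 0)
  st <- baseline_state()
  m1 <- mean_conductance_densities(st, tree, syn)
  st2 <- presynaptic_state(0.4, 2.4, 0.4, 2.4, 0.05)
  m2 <- mean_conductance_densities(st2, tree, syn)
  expect_equal(m2$areal$ge, 2 * m1$areal$ge)
  expect_equal(m2$areal$gi, 2 * m1$areal$gi)
  expect_equal(m2$soma_Gi, 2 * m1$soma_Gi)
  # areal values nu * Q * tau * density: in these units (Hz, nS, ms,
  # synapses per 100 um^2 -> uS/cm^2) the conversion factor is exactly 1
  expect_equal(m1$areal$ge[1], 0.2 * 0.7 * 5 * 30, tolerance = 1e-12)
  expect_equal(m1$areal$gi[2], 1.2 * 1.5 * 5 * 6, tolerance = 1e-12)
  # aggregated linear density grows with the summed perimeter of the
  # deeper generations
  lin <- m1$linear(c(50, 500))
  expect_gt(lin$ge[2], lin$ge[1])
})

test_that("quantal rescaling keeps the somatic efficacy invariant", {
  syn <- med_syn(); pas <- med_passive()
  expect_equal(rescale_quantals(syn, 300, 300)$Qep, syn$Qep)
  expect_equal(rescale_quantals(syn, 600, 300)$Qep, syn$Qep / 2)
  R_ref <- input_resistance(med_tree(), pas)
  facs <- seq(0.6, 1.8, length.out = 10)
  eff <- vapply(facs, function(f) {
    R <- input_resistance(size_comodulation(f), pas)
    rescale_quantals(syn, R, R_ref)$Qep * R
  }, numeric(1))
  expect_lt(diff(range(eff)) / mean(eff), 1e-10)
})
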