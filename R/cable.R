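# Piecewise-cable engine on the reduced (path-coordinate) tree.
#
# By branch symmetry every quantity depends only on the path distance x from
# the soma, so the whole arborescence collapses onto a single piecewise
# cable whose per-length electrical densities aggregate the 2^(b-1) parallel
# branches of generation b. Because synapse densities are areal and Rall's
# rule fixes the diameters, the propagation constant gamma is continuous in
# electrotonic terms within a domain while the characteristic admittance
# jumps at generation boundaries; both are handled segment by segment.
# All internal quantities are SI (m, s, S, F, V).

# mean synaptic conductance per synapse is nu * Q * tau (Campbell's theorem,
# independent of the synchrony s since coincidences conserve the event rate)
.mean_area_densities <- function(state, syn) {
  list(
    ge_p = (syn$De_tree * .per_100um2) * state$nu_ep *
      (syn$Qep * .nS) * (syn$tau_e * .ms),
    gi_p = (syn$Di_tree * .per_100um2) * state$nu_ip *
      (syn$Qip * .nS) * (syn$tau_i * .ms),
    ge_d = (syn$De_tree * .per_100um2) * state$nu_ed *
      (syn$Qed * .nS) * (syn$tau_e * .ms),
    gi_d = (syn$Di_tree * .per_100um2) * state$nu_id *
      (syn$Qid * .nS) * (syn$tau_i * .ms)
  )
}

# Build the aggregated segment table + lumped soma. state = NULL gives the
# resting (synapse-free) membrane.
.cable_segments <- function(tree, passive, syn = NULL, state = NULL) {
  GL <- passive$GL * .uS_cm2
  Cm <- passive$Cm * .uF_cm2
  Ri <- passive$Ri * .Ohm_cm
  EL <- passive$EL * .mV
  lt <- tree$lt * .um
  lp <- tree$lp * .um

  dens <- if (!is.null(state)) .mean_area_densities(state, syn) else
    list(ge_p = 0, gi_p = 0, ge_d = 0, gi_d = 0)
  Ee <- if (!is.null(syn)) syn$Ee * .mV else 0
  Ei <- if (!is.null(syn)) syn$Ei * .mV else 0

  # breakpoints: generation boundaries and the proximal/distal boundary
  brk <- sort(unique(c(tree$gen$x0 * .um, lt, lp)))
  brk <- brk[brk >= 0 & brk <= lt]
  x0 <- brk[-length(brk)]; x1 <- brk[-1]
  keep <- (x1 - x0) > 1e-12
  x0 <- x0[keep]; x1 <- x1[keep]
  mid <- (x0 + x1) / 2
  b <- findInterval(mid, tree$gen$x0 * .um)
  d <- tree$gen$diam[b] * .um
  n <- tree$gen$n[b]
  distal <- mid > lp

  ge <- ifelse(distal, dens$ge_d, dens$ge_p)
  gi <- ifelse(distal, dens$gi_d, dens$gi_p)
  Ga <- GL + ge + gi                         # total areal conductance, S/m^2
  g <- n * pi * d * Ga                       # aggregated S/m
  cc <- n * pi * d * Cm                      # aggregated F/m
  ri <- 4 * Ri / (n * pi * d^2)              # aggregated Ohm/m
  v0 <- (GL * EL + ge * Ee + gi * Ei) / Ga

  segs <- data.frame(x0 = x0, x1 = x1, len = x1 - x0, b = b, n = n, d = d,
                     distal = distal, g = g, c = cc, ri = ri, v0 = v0,
                     lambda = 1 / sqrt(ri * g),
                     tau_eff = Cm / Ga)

  A_s <- pi * (tree$dS * .um) * (tree$lS * .um)
  GL_s <- GL * A_s
  Ni_s <- if (!is.null(syn)) A_s * (syn$Di_soma * .per_100um2) else 0
  GI_s <- if (!is.null(state))
    Ni_s * state$nu_ip * (syn$QiS * .nS) * (syn$tau_i * .ms) else 0
  G_s <- GL_s + GI_s
  v0_s <- (GL_s * EL + GI_s * Ei) / G_s

  list(segs = segs,
       soma = list(A = A_s, GL = GL_s, GI = GI_s, G = G_s, C = Cm * A_s,
                   v0 = v0_s, Ni = Ni_s),
       lt = lt, lp = lp, EL = EL, Ee = Ee, Ei = Ei,
       tree = tree, passive = passive, syn = syn, state = state)
}

# two-port admittance propagation through a uniform cable piece:
# admittance seen at the near end given load Yload at the far end
.prop_admittance <- function(Yload, gamma, Yc, len) {
  th <- tanh(gamma * len)
  Yc * (Yload + Yc * th) / (Yc + Yload * th)
}

# voltage attenuation across a uniform piece towards a load Yload:
# v(near load) / v(far) = 1 / (cosh(gamma len) + (Yload/Yc) sinh(gamma len))
.prop_attenuation <- function(Yload, gamma, Yc, len) {
  gl <- gamma * len
  1 / (cosh(gl) + (Yload / Yc) * sinh(gl))
}

.soma_admittance <- function(cab, omega) {
  cab$soma$G + 1i * omega * cab$soma$C
}

# admittance of the whole arborescence seen from the soma (complex, per omega)
.tree_admittance <- function(cab, omega) {
  K <- nrow(cab$segs)
  Y <- rep(0 + 0i, length(omega))
  for (k in K:1) {
    s <- cab$segs[k, ]
    y <- s$g + 1i * omega * s$c
    gamma <- sqrt(s$ri * y)
    Yc <- sqrt(y / s$ri)
    Y <- .prop_admittance(Y, gamma, Yc, s$len)
  }
  Y
}

# Precompute, for a frequency grid, everything needed to evaluate transfer
# impedances Z_T(x -> soma) at arbitrary positions: per-segment gamma/Yc
# (matrices K x nw), tip-ward admittance Yup at each segment's proximal end,
# soma-ward admittance Ydown, and cumulative somapetal attenuation.
.transfer_setup <- function(cab, omega) {
  K <- nrow(cab$segs); nw <- length(omega)
  gam <- Yc <- matrix(0 + 0i, K, nw)
  for (k in seq_len(K)) {
    s <- cab$segs[k, ]
    y <- s$g + 1i * omega * s$c
    gam[k, ] <- sqrt(s$ri * y)
    Yc[k, ] <- sqrt(y / s$ri)
  }
  Yup <- matrix(0 + 0i, K + 1, nw)     # Yup[k,]: looking tip-ward at x0_k
  for (k in K:1)
    Yup[k, ] <- .prop_admittance(Yup[k + 1, ], gam[k, ], Yc[k, ],
                                 cab$segs$len[k])
  Ydown <- matrix(0 + 0i, K, nw)       # looking soma-ward at x0_k
  Ydown[1, ] <- .soma_admittance(cab, omega)
  if (K > 1)
    for (k in seq_len(K - 1))
      Ydown[k + 1, ] <- .prop_admittance(Ydown[k, ], gam[k, ], Yc[k, ],
                                         cab$segs$len[k])
  cumA <- matrix(1 + 0i, K, nw)        # attenuation x0_k -> soma
  if (K > 1)
    for (k in seq_len(K - 1))
      cumA[k + 1, ] <- cumA[k, ] *
        .prop_attenuation(Ydown[k, ], gam[k, ], Yc[k, ], cab$segs$len[k])
  list(cab = cab, omega = omega, gam = gam, Yc = Yc,
       Yup = Yup, Ydown = Ydown, cumA = cumA,
       Zin = 1 / (Ydown[1, ] + Yup[1, ]))
}

# transfer impedance (V at soma per unit current injected at x), complex
# vector over the setup's frequency grid; x in metres from the soma
.transfer_impedance <- function(ts, x) {
  cab <- ts$cab
  if (x < 0 || x > cab$lt + 1e-12) stop("position outside the tree")
  if (x <= 0) return(ts$Zin)
  k <- findInterval(x, cab$segs$x0, rightmost.closed = TRUE)
  k <- min(max(k, 1), nrow(cab$segs))
  d0 <- x - cab$segs$x0[k]
  d1 <- cab$segs$x1[k] - x
  Yr <- .prop_admittance(ts$Yup[k + 1, ], ts$gam[k, ], ts$Yc[k, ], d1)
  Yl <- .prop_admittance(ts$Ydown[k, ], ts$gam[k, ], ts$Yc[k, ], d0)
  Ax <- .prop_attenuation(ts$Ydown[k, ], ts$gam[k, ], ts$Yc[k, ], d0)
  Ax * ts$cumA[k, ] / (Yl + Yr)
}

# Stationary piecewise solution: v_k(x) = v0_k + A_k cosh(u) + B_k sinh(u),
# u = (x - x0_k)/lambda_k. Boundary rows: lumped-soma current balance at
# x = 0, continuity of v and axial current at interfaces, sealed tip.
.stationary_profile <- function(cab) {
  segs <- cab$segs
  K <- nrow(segs)
  M <- matrix(0, 2 * K, 2 * K)
  rhs <- numeric(2 * K)
  iA <- function(k) 2 * k - 1
  iB <- function(k) 2 * k
  # soma: (1/ri_1) v'(0) = G_s (v(0) - v0_s)
  M[1, iA(1)] <- -cab$soma$G
  M[1, iB(1)] <- 1 / (segs$ri[1] * segs$lambda[1])
  rhs[1] <- cab$soma$G * (segs$v0[1] - cab$soma$v0)
  row <- 2
  if (K > 1) for (k in seq_len(K - 1)) {
    U <- segs$len[k] / segs$lambda[k]
    ch <- cosh(U); sh <- sinh(U)
    # continuity of v
    M[row, iA(k)] <- ch; M[row, iB(k)] <- sh; M[row, iA(k + 1)] <- -1
    rhs[row] <- segs$v0[k + 1] - segs$v0[k]
    row <- row + 1
    # continuity of axial current (aggregated)
    ck <- 1 / (segs$ri[k] * segs$lambda[k])
    ck1 <- 1 / (segs$ri[k + 1] * segs$lambda[k + 1])
    M[row, iA(k)] <- ck * sh; M[row, iB(k)] <- ck * ch
    M[row, iB(k + 1)] <- -ck1
    row <- row + 1
  }
  UK <- segs$len[K] / segs$lambda[K]
  M[row, iA(K)] <- sinh(UK); M[row, iB(K)] <- cosh(UK)
  coef <- solve(M, rhs)
  A <- coef[seq(1, 2 * K, by = 2)]
  B <- coef[seq(2, 2 * K, by = 2)]
  mu_fun <- function(x) {  # x in metres, vectorized; returns volts
    k <- pmin(pmax(findInterval(x, segs$x0, rightmost.closed = TRUE), 1), K)
    u <- (x - segs$x0[k]) / segs$lambda[k]
    segs$v0[k] + A[k] * cosh(u) + B[k] * sinh(u)
  }
  list(A = A, B = B, mu = mu_fun, mu_soma = segs$v0[1] + A[1])
}
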