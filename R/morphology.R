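# Symmetric Rall-branched morphology: soma cylinder + B generations of
# branches, generation b holding 2^(b-1) branches of length lt/B and
# diameter d_b = 2^(-2(b-1)/3) * dt (so that 2 * d_{b+1}^{3/2} = d_b^{3/2}).

#' Build a symmetric Rall-branched dendritic tree
#'
#' Constructs the morphology used throughout the package: an isopotential
#' cylindrical soma in parallel with a dendritic arborescence of `B`
#' generations of symmetric branches whose diameters follow Rall's 3/2
#' branching rule. All branches of generation `b` share length `lt/B` and
#' diameter `2^(-2(b-1)/3) * dt`. The path coordinate `x` runs from the soma
#' (`x = 0`) to the sealed tips (`x = lt`); the proximal/distal boundary sits
#' at `lp = fprox * lt`.
#'
#' @param B number of branch generations (integer >= 1).
#' @param lt total tree length along the path from soma to tip (um).
#' @param dt diameter of the root branch (um).
#' @param lS soma length (um).
#' @param dS soma diameter (um).
#' @param fprox proximal tree fraction, strictly inside (0, 1).
#' @return An object of class `tree_morphology` with per-generation
#'   accessors in `$gen` (a data.frame with columns `b`, `n`, `diam`,
#'   `length`, `x0`, `x1`).
#' @examples
#' tree <- build_tree()
#' tree$gen$diam[2] # generation-2 diameter, 2^(-2/3) * 2.25 um
#' @export
build_tree <- function(B = 5, lt = 550, dt = 2.25, lS = 5, dS = 15,
                       fprox = 7 / 8) {
  if (!is.numeric(B) || length(B) != 1 || B < 1 || B != round(B))
    stop("B must be a positive integer")
  geom <- c(lt = lt, dt = dt, lS = lS, dS = dS)
  bad <- names(geom)[!is.finite(geom) | geom <= 0]
  if (length(bad))
    stop("non-positive geometry parameter(s): ", paste(bad, collapse = ", "))
  if (fprox <= 0 || fprox >= 1)
    stop("fprox must lie strictly inside (0, 1)")
  b <- seq_len(B)
  gen <- data.frame(
    b = b,
    n = 2^(b - 1),
    diam = 2^(-2 * (b - 1) / 3) * dt,
    length = lt / B,
    x0 = (b - 1) * lt / B,
    x1 = b * lt / B
  )
  structure(list(B = as.integer(B), lt = lt, dt = dt, lS = lS, dS = dS,
                 fprox = fprox, lp = fprox * lt, gen = gen),
            class = "tree_morphology")
}

#' @export
print.tree_morphology <- function(x, ...) {
  cat(sprintf(
    "Rall tree: B=%d generations, lt=%.4g um, dt=%.4g um, soma %gx%g um, fprox=%.4g\n",
    x$B, x$lt, x$dt, x$lS, x$dS, x$fprox))
  invisible(x)
}

#' Membrane areas of soma and tree
#'
#' Lateral (open-cylinder) membrane areas: the soma contributes
#' `pi * dS * lS`; generation `b` contributes `2^(b-1) * pi * d_b * (lt/B)`.
#'
#' @param tree a `tree_morphology`.
#' @return A list with `soma` (um^2), `per_generation` (um^2 vector) and
#'   `tree_total` (um^2).
#' @export
membrane_areas <- function(tree) {
  stopifnot(inherits(tree, "tree_morphology"))
  per_gen <- tree$gen$n * pi * tree$gen$diam * tree$gen$length
  list(soma = pi * tree$dS * tree$lS,
       per_generation = per_gen,
       tree_total = sum(per_gen))
}

#' Synapse counts from areal densities
#'
#' Real-valued synapse counts (area times density; integer rounding only
#' happens at simulator discretization time) and the excitatory-to-inhibitory
#' count ratio.
#'
#' @param tree a `tree_morphology`.
#' @param syn a `synaptic_params`.
#' @return A list with `Ne_tree`, `Ni_tree`, `Ni_soma`, `Ne_soma` and
#'   `ratio` = Ne / (Ni_tree + Ni_soma).
#' @export
synapse_counts <- function(tree, syn = synaptic_params()) {
  stopifnot(inherits(tree, "tree_morphology"), inherits(syn, "synaptic_params"))
  ar <- membrane_areas(tree)
  Ne_tree <- ar$tree_total * syn$De_tree / 100
  Ni_tree <- ar$tree_total * syn$Di_tree / 100
  Ni_soma <- ar$soma * syn$Di_soma / 100
  Ne_soma <- ar$soma * syn$De_soma / 100
  Ni <- Ni_tree + Ni_soma
  list(Ne_tree = Ne_tree, Ni_tree = Ni_tree, Ni_soma = Ni_soma,
       Ne_soma = Ne_soma,
       ratio = if (Ni > 0) (Ne_tree + Ne_soma) / Ni else NA_real_)
}

#' Co-modulate the size of the morphology
#'
#' Size variations of the cellular model are a linear co-modulation of the
#' tree length `lt`, the root diameter `dt` and the soma length `lS`; the
#' generation count, soma diameter and proximal fraction stay fixed. A
#' factor above one yields a larger cell with a strictly lower somatic input
#' resistance.
#'
#' @param size_factor scale factor, within `range`.
#' @param reference the medium-size reference `tree_morphology`.
#' @param range admissible factor range (default `c(0.5, 2)`).
#' @return A `tree_morphology`.
#' @export
size_comodulation <- function(size_factor, reference = build_tree(),
                              range = c(0.5, 2)) {
  if (!is.finite(size_factor) || size_factor < range[1] ||
      size_factor > range[2])
    stop(sprintf("size_factor %.3g outside configured range [%g, %g]",
                 size_factor, range[1], range[2]))
  build_tree(B = reference$B,
             lt = reference$lt * size_factor,
             dt = reference$dt * size_factor,
             lS = reference$lS * size_factor,
             dS = reference$dS,
             fprox = reference$fprox)
}

#' Map somatic input resistance to a size factor
#'
#' Inverts the monotonically decreasing map `size_factor -> R_in` defined by
#' [size_comodulation()] and the analytic resting input resistance, by 1-D
#' root finding. The round trip `R_in(resistance_to_size(R))` agrees with
#' `R` to a relative error below 1e-6.
#'
#' @param R_in target somatic input resistance (MOhm).
#' @param passive a `passive_params`.
#' @param reference medium-size reference morphology.
#' @param range admissible size-factor range.
#' @return The size factor (scalar).
#' @seealso [input_resistance()]
#' @export
resistance_to_size <- function(R_in, passive = passive_params(),
                               reference = build_tree(), range = c(0.5, 2)) {
  stopifnot(is.finite(R_in), R_in > 0)
  rfun <- function(f)
    input_resistance(size_comodulation(f, reference, range), passive)
  lo <- rfun(range[2]) # largest cell -> smallest resistance
  hi <- rfun(range[1])
  if (R_in < lo || R_in > hi)
    stop(sprintf(
      "R_in = %.4g MOhm outside the attainable range [%.4g, %.4g] MOhm",
      R_in, lo, hi))
  uniroot(function(f) rfun(f) - R_in, interval = range,
          tol = .Machine$double.eps^0.6)$root
}

#' Export the discretized morphology as SWC
#'
#' Writes the standard seven SWC columns (id, type, x, y, z, radius,
#' parent), with the soma as a single type-1 sample and dendritic branches
#' laid out deterministically in the z = 0 plane, each generation fanning
#' within the angular sector of its parent.
#'
#' @param tree a `tree_morphology`.
#' @param path output file path.
#' @param points_per_branch samples per branch (>= 2).
#' @return Invisibly, the SWC table (data.frame).
#' @export
write_swc <- function(tree, path, points_per_branch = 2) {
  stopifnot(inherits(tree, "tree_morphology"), points_per_branch >= 2)
  rows <- list(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                          radius = tree$dS / 2, parent = -1))
  next_id <- 2
  # branch (b, j): j in 0..(2^(b-1)-1); parent branch (b-1, floor(j/2))
  tip_id <- list(); tip_xy <- list()
  key <- function(b, j) paste(b, j)
  for (b in seq_len(tree$B)) {
    g <- tree$gen[b, ]
    for (j in seq_len(g$n) - 1) {
      # angular sector: branch j of generation b spans a fan around vertical
      ang <- pi / 2 + (j + 0.5) / g$n * pi - pi / 2 - pi / 4 * 0
      ang <- (j + 0.5) / g$n * pi  # in (0, pi), deterministic fan
      if (b == 1) {
        p_id <- 1; p_xy <- c(0, 0)
      } else {
        p_id <- tip_id[[key(b - 1, j %/% 2)]]
        p_xy <- tip_xy[[key(b - 1, j %/% 2)]]
      }
      ts <- seq_len(points_per_branch) / points_per_branch
      xs <- p_xy[1] + cos(ang) * g$length * ts
      ys <- p_xy[2] + sin(ang) * g$length * ts
      ids <- next_id + seq_along(ts) - 1
      rows[[length(rows) + 1]] <- data.frame(
        id = ids, type = 3, x = xs, y = ys, z = 0,
        radius = g$diam / 2,
        parent = c(p_id, ids[-length(ids)]))
      tip_id[[key(b, j)]] <- ids[length(ids)]
      tip_xy[[key(b, j)]] <- c(xs[length(xs)], ys[length(ys)])
      next_id <- next_id + length(ts)
    }
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export of the symmetric Rall-branched model", con)
  utils::write.table(format(tab, digits = 8, scientific = FALSE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(tab)
}
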