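# Independent oracles used by the tests. These deliberately avoid the
# package's analytic code paths: finite differences, brute-force grids,
# and direct numeric minimization.

coords_vec <- function(geom) as.numeric(t(geom$coords))

geom_with <- function(geom, xvec) {
  geometry(geom$symbols, matrix(xvec, ncol = 3L, byrow = TRUE))
}

# central finite-difference rows of the B-matrix
fd_b_matrix <- function(geom, prims, h = 1e-5) {
  x0 <- coords_vec(geom)
  cols <- vapply(seq_along(x0), function(j) {
    xp <- x0; xp[j] <- xp[j] + h
    xm <- x0; xm[j] <- xm[j] - h
    (measure_primitives(geom_with(geom, xp), prims) -
       measure_primitives(geom_with(geom, xm), prims)) / (2 * h)
  }, numeric(length(prims)))
  matrix(cols, nrow = length(prims))
}

# central finite-difference gradient of a calculator's energy
fd_energy_gradient <- function(calc, geom, h = 1e-5) {
  x0 <- coords_vec(geom)
  vapply(seq_along(x0), function(j) {
    xp <- x0; xp[j] <- xp[j] + h
    xm <- x0; xm[j] <- xm[j] - h
    (evaluate(calc, geom_with(geom, xp))$energy -
       evaluate(calc, geom_with(geom, xm))$energy) / (2 * h)
  }, numeric(1L))
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                            3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                            3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)

# brute-force rigid superposition: centroid match + dense Euler-angle grid
brute_force_align_rmsd <- function(reference, mobile, ngrid = 24L) {
  P <- mobile$coords; Q <- reference$coords
  P0 <- sweep(P, 2L, colMeans(P))
  Q0 <- sweep(Q, 2L, colMeans(Q))
  angs <- seq(0, 2 * pi, length.out = ngrid + 1L)[-(ngrid + 1L)]
  best <- Inf
  for (a in angs) for (b in angs[seq_len(ngrid / 2L)]) for (cc in angs) {
    R <- rot_z(a) %*% rot_y(b) %*% rot_x(cc)
    r <- sqrt(sum((P0 %*% t(R) - Q0)^2) / nrow(P))
    if (r < best) best <- r
  }
  best
}

# Newton search for a stationary point of the Mueller-Brown surface,
# using the analytic gradient and a finite-difference Hessian
mb_grad <- function(x, y) {
  calc <- mb_calculator()
  evaluate(calc, geometry("H", c(x, y, 0)))$gradient[1:2]
}

newton_stationary_mb <- function(xy0, tol = 1e-12, maxit = 200L) {
  x <- xy0
  h <- 1e-6
  for (i in seq_len(maxit)) {
    g <- mb_grad(x[1L], x[2L])
    H <- matrix(0, 2L, 2L)
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + h
      xm <- x; xm[j] <- xm[j] - h
      H[, j] <- (mb_grad(xp[1L], xp[2L]) - mb_grad(xm[1L], xm[2L])) / (2 * h)
    }
    dx <- solve(H, -g)
    x <- x + dx
    if (max(abs(dx)) < tol) break
  }
  list(xy = x, hessian = H, gradient = mb_grad(x[1L], x[2L]))
}

# shortest-arc circular interpolation between two angles (radians)
circular_interp <- function(a, b, f) {
  d <- (b - a + pi) %% (2 * pi) - pi
  if (d <= -pi) d <- d + 2 * pi
  ang <- a + f * d
  w <- (ang + pi) %% (2 * pi) - pi
  if (w <= -pi) w + 2 * pi else w
}

# small randomly distorted test geometries spanning the fixture templates
random_fixture_geometries <- function(n, seed = 42L) {
  specs <- list(
    fixture_spec("bent-triatomic"),
    fixture_spec("four-atom-torsion", torsion = 60),
    fixture_spec("four-atom-torsion", torsion = 150),
    fixture_spec("butane-like", torsion = -60)
  )
  out <- vector("list", n)
  for (i in seq_len(n)) {
    base <- build_fixture(specs[[(i - 1L) %% length(specs) + 1L]])
    out[[i]] <- perturb(base, rigid = TRUE, noise_sigma = 0.05,
                        seed = seed + i)
  }
  out
}

# standard butane-like anti -> gauche reaction fixture + matched FF.
# The exact-180-degree anti endpoint triggers the trans-planar torsion
# prune, so the resulting primitive set is redundant (7 primitives, 6
# delocalized coordinates).
butane_reaction <- function() {
  pair <- make_pair(fixture_spec("butane-like", torsion = 180),
                    fixture_spec("butane-like", torsion = 60))
  list(reactant = pair$reactant, product = pair$product,
       spec = butane_toyff())
}

# variant with a 170-degree reactant: no pruning fires, the primitive set
# is exactly nonredundant (6 primitives = 3N - 6), so linear targets in
# the primitives are exactly realizable. Used for linearity/symmetry
# invariants, which only hold for consistent (nonredundant) targets.
butane_reaction_clean <- function() {
  pair <- make_pair(fixture_spec("butane-like", torsion = 170),
                    fixture_spec("butane-like", torsion = 60))
  list(reactant = pair$reactant, product = pair$product,
       spec = butane_toyff())
}

# dense 1-D scan of the toy-FF torsional term between two endpoint values
torsion_scan_max <- function(spec, from_deg, to_deg, n = 2001L) {
  tr <- spec$torsions[1L, ]
  phis <- seq(from_deg, to_deg, length.out = n) * pi / 180
  e <- tr$V / 2 * (1 + cos(tr$n * phis - tr$gamma))
  phis[which.max(e)] * 180 / pi
}
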