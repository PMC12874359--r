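test_that("detect_primitives assigns bonds, angles, torsions and fragment connectors", {
  d <- build_fixture(fixture_spec("diatomic"))
  pd <- detect_primitives(d)
  expect_length(pd, 1L)
  expect_equal(pd[[1L]]$kind, "bond")

  w <- build_fixture(fixture_spec("bent-triatomic"))
  kinds <- vapply(detect_primitives(w), function(p) p$kind, character(1L))
  expect_equal(sort(kinds), c("angle", "bond", "bond"))

  # two separated H2 fragments: 2 bonds + 1 connecting distance, and the
  # connector participates in the graph so the system is orientable
  tf <- build_fixture(fixture_spec("two-fragment", separation = 5))
  p <- detect_primitives(tf)
  kinds <- vapply(p, function(x) x$kind, character(1L))
  expect_equal(sum(kinds == "bond"), 2L)
  expect_equal(sum(kinds == "distance"), 1L)
  conn <- p[[which(kinds == "distance")]]
  expect_equal(sort(conn$atoms), c(2L, 3L))
})

test_that("build_ic_system unions endpoints and applies the pruning rules", {
  # bent pair: no pruning
  w1 <- build_fixture(fixture_spec("bent-triatomic", angle = 104.5))
  w2 <- build_fixture(fixture_spec("bent-triatomic", angle = 95))
  ics <- build_ic_system(w1, w2)
  kinds <- vapply(ics$primitives, function(p) p$kind, character(1L))
  expect_equal(sort(kinds), c("angle", "bond", "bond"))
  expect_equal(nrow(ics$prune_log), 0L)

  # linear endpoint: angle replaced by two orthogonal linear bends
  lin <- build_fixture(fixture_spec("linear-triatomic", angle = 180))
  bent <- build_fixture(fixture_spec("linear-triatomic", angle = 150))
  ics <- build_ic_system(lin, bent)
  kinds <- vapply(ics$primitives, function(p) p$kind, character(1L))
  expect_equal(sum(kinds == "linear_bend"), 2L)
  expect_equal(sum(kinds == "angle"), 0L)
  lb <- ics$primitives[kinds == "linear_bend"]
  expect_lt(abs(sum(lb[[1L]]$axis * lb[[2L]]$axis)), 1e-10)

  # over-bent other endpoint: the linear-bend pair itself is pruned
  vbent <- build_fixture(fixture_spec("linear-triatomic", angle = 100))
  ics <- build_ic_system(lin, vbent)
  kinds <- vapply(ics$primitives, function(p) p$kind, character(1L))
  expect_equal(sum(kinds == "linear_bend"), 0L)
  expect_true("linear_bend_overbent" %in% ics$prune_log$rule)

  # near-linear chain in one endpoint kills all torsions and the rescue
  # scan, so the set falls back to all unique atom-atom distances
  chain_lin <- geometry(rep("C", 4),
                        rbind(c(0, 0, 0), c(1.5, 0, 0),
                              c(3.0, 0, 0), c(4.5, 0, 0)))
  chain_bent <- build_fixture(fixture_spec("four-atom-torsion", torsion = 60))
  ics <- build_ic_system(chain_lin, chain_bent)
  kinds <- vapply(ics$primitives, function(p) p$kind, character(1L))
  expect_true(all(kinds == "distance"))
  expect_length(ics$primitives, 6L)  # all 4*3/2 unique pairs
  expect_true("no_valid_torsion" %in% ics$prune_log$rule)

  expect_error(build_ic_system(w1, build_fixture(fixture_spec("diatomic"))),
               "atom count")
})

test_that("pruning is deterministic and the trans-planar torsion rule adds an A-D distance", {
  r <- build_fixture(fixture_spec("four-atom-torsion", torsion = 178))
  p <- build_fixture(fixture_spec("four-atom-torsion", torsion = 60))
  ics1 <- build_ic_system(r, p)
  ics2 <- build_ic_system(r, p)
  expect_identical(vapply(ics1$primitives, format, character(1L)),
                   vapply(ics2$primitives, format, character(1L)))
  expect_true("trans_planar_torsion" %in% ics1$prune_log$rule)
  kinds <- vapply(ics1$primitives, function(x) x$kind, character(1L))
  # the 1-4 pair distance stands in for the removed torsion (or the
  # rescue scan found a replacement torsion); either way no torsion with
  # a trans-planar endpoint value survives
  surviving_tors <- ics1$primitives[kinds == "torsion"]
  for (tp in surviving_tors) {
    expect_lt(abs(measure_primitives(r, tp)), 175 * pi / 180)
    expect_lt(abs(measure_primitives(p, tp)), 175 * pi / 180)
  }
})

test_that("measure_primitives returns documented values and units", {
  d <- build_fixture(fixture_spec("diatomic", r = 1.5))
  expect_equal(measure_primitives(d, primitive("bond", 1:2)), 1.5,
               tolerance = 1e-12)

  ra <- build_fixture(fixture_spec("bent-triatomic", angle = 90))
  expect_equal(measure_primitives(ra, primitive("angle", c(2L, 1L, 3L))),
               pi / 2, tolerance = 1e-12)

  tg <- build_fixture(fixture_spec("four-atom-torsion", torsion = 60))
  expect_equal(measure_primitives(tg, primitive("torsion", 1:4)),
               pi / 3, tolerance = 1e-10)

  # collinear internal atoms make a torsion undefined, with a clear error
  lin <- geometry(rep("C", 4),
                  rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0), c(4.5, 1, 0)))
  expect_error(measure_primitives(lin, primitive("torsion", 1:4)),
               "torsion")
})

test_that("wilson_b_matrix rows are exact analytic derivatives", {
  # diatomic along x: the classic (-1,0,0,+1,0,0) row
  d <- build_fixture(fixture_spec("diatomic", r = 1.3))
  B <- wilson_b_matrix(d, list(primitive("bond", 1:2)))
  expect_equal(B[1L, ], c(-1, 0, 0, 1, 0, 0), tolerance = 1e-12)

  # uniform translation is in the null space
  g <- perturb(build_fixture(fixture_spec("butane-like", torsion = 60)),
               rigid = FALSE, noise_sigma = 0.05, seed = 2L)
  prims <- detect_primitives(g)
  B <- wilson_b_matrix(g, prims)
  for (ax in 1:3) {
    tvec <- rep(0, 12); tvec[seq(ax, 12, by = 3)] <- 1
    expect_lt(max(abs(B %*% tvec)), 1e-10)
  }

  # finite-difference oracle on a random bent triatomic
  tri <- perturb(build_fixture(fixture_spec("bent-triatomic")),
                 rigid = TRUE, noise_sigma = 0.05, seed = 9L)
  prims <- detect_primitives(tri)
  expect_lt(max(abs(wilson_b_matrix(tri, prims) - fd_b_matrix(tri, prims))),
            1e-6)
})

test_that("delocalize splits redundant and nonredundant subspaces by rank", {
  w <- build_fixture(fixture_spec("bent-triatomic"))
  prims <- detect_primitives(w)  # 2 bonds + 1 angle
  dl <- delocalize(wilson_b_matrix(w, prims))
  expect_equal(ncol(dl$U), 3L)  # = 3N - 6
  expect_lt(max(abs(crossprod(dl$U) - diag(3L))), 1e-10)
  # rank oracle via singular values of B_prim
  expect_equal(ncol(dl$U), sum(svd(wilson_b_matrix(w, prims))$d > 1e-8))

  # adding the redundant H..H distance leaves the nonredundant count at 3
  prims4 <- c(prims, list(primitive("distance", c(2L, 3L))))
  dl4 <- delocalize(wilson_b_matrix(w, prims4))
  expect_equal(ncol(dl4$U), 3L)
  expect_equal(sum(dl4$eigenvalues <= dl4$eig_threshold), 1L)
  expect_true(all(dl4$eigenvalues >= -1e-12))  # G is positive semidefinite
})

test_that("b_pseudo_inverse satisfies the generalized-inverse identities", {
  # orthonormal rows: pseudo-inverse equals B
  B <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(b_pseudo_inverse(B), B, tolerance = 1e-12)

  # single row: B / ||B||^2
  b1 <- matrix(c(3, 0, 4, 0, 0, 0), nrow = 1L)
  expect_equal(b_pseudo_inverse(b1), b1 / 25, tolerance = 1e-12)

  # random full-rank case: B %*% t(pinv) = I
  set.seed(31)
  B <- matrix(rnorm(3 * 9), 3L, 9L)
  expect_lt(max(abs(B %*% t(b_pseudo_inverse(B)) - diag(3L))), 1e-8)
})

test_that("cartesian_from_internal solves targets and round-trips displacements", {
  # fixed point: target = current internals
  w <- build_fixture(fixture_spec("bent-triatomic"))
  ics <- build_ic_system(w, w)
  q0 <- measure_primitives(w, ics$primitives)
  out <- cartesian_from_internal(q0, w, ics)
  expect_true(attr(out, "converged"))
  expect_lte(attr(out, "iterations"), 2L)
  expect_equal(out$coords, w$coords, tolerance = 1e-7)

  # diatomic stretch 1.0 -> 1.2
  d1 <- build_fixture(fixture_spec("diatomic", r = 1.0))
  d2 <- build_fixture(fixture_spec("diatomic", r = 1.4))
  icsd <- build_ic_system(d1, d2)
  g <- cartesian_from_internal(1.2, d1, icsd)
  expect_equal(measure_primitives(g, icsd$primitives), 1.2, tolerance = 1e-7)

  # torsion rotated by 20 degrees, re-measure oracle
  tA <- build_fixture(fixture_spec("butane-like", torsion = 60))
  tB <- build_fixture(fixture_spec("butane-like", torsion = 170))
  icst <- build_ic_system(tA, tB)
  q <- measure_primitives(tA, icst$primitives)
  it <- which(vapply(icst$primitives, function(p) p$kind == "torsion",
                     logical(1L)))
  q[it] <- q[it] + 20 * pi / 180
  g <- cartesian_from_internal(q, tA, icst)
  expect_true(attr(g, "converged"))
  expect_lt(abs(measure_primitives(g, icst$primitives)[it] - q[it]), 1e-6)
})

test_that("back-transformation round-trips random delocalized displacements", {
  tA <- build_fixture(fixture_spec("butane-like", torsion = 60))
  tB <- build_fixture(fixture_spec("butane-like", torsion = 170))
  ics <- build_ic_system(tA, tB)
  q0 <- measure_primitives(tA, ics$primitives)
  m <- ncol(ics$U)
  set.seed(17)
  for (rep in 1:8) {
    dq_dlc <- rnorm(m)
    dq_dlc <- dq_dlc / sqrt(sum(dq_dlc^2)) * runif(1, 0.05, 0.3)
    target <- q0 + as.numeric(ics$U %*% dq_dlc)
    g <- cartesian_from_internal(target, tA, ics)
    expect_true(attr(g, "converged"))
    expect_lt(max(abs(measure_primitives(g, ics$primitives) - target)), 1e-6)
  }
})

test_that("B-matrix annihilates infinitesimal rigid rotations and Eq.-6 steps are consistent", {
  g <- perturb(build_fixture(fixture_spec("butane-like", torsion = 60)),
               rigid = FALSE, noise_sigma = 0.03, seed = 4L)
  prims <- detect_primitives(g)
  B <- wilson_b_matrix(g, prims)
  cen <- colMeans(g$coords)
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    field <- as.numeric(apply(g$coords, 1L, function(x) {
      d <- x - cen
      c(ax[2] * d[3] - ax[3] * d[2],
        ax[3] * d[1] - ax[1] * d[3],
        ax[1] * d[2] - ax[2] * d[1])
    }))
    expect_lt(max(abs(B %*% field)), 1e-8)
  }

  dl <- delocalize(B)
  Binv <- b_pseudo_inverse(dl$B)
  set.seed(8)
  for (rep in 1:5) {
    dq <- rnorm(ncol(dl$U))
    dx <- as.numeric(t(Binv) %*% dq)
    expect_lt(max(abs(dl$B %*% dx - dq)), 1e-8)
  }
})

test_that("the primitive dump lists values at both endpoints and the prune log", {
  lin <- build_fixture(fixture_spec("linear-triatomic", angle = 180))
  bent <- build_fixture(fixture_spec("linear-triatomic", angle = 150))
  ics <- build_ic_system(lin, bent)
  rep <- dump_primitives(ics, lin, bent)
  expect_true(any(grepl("bond", rep)))
  expect_true(any(grepl("near_linear_angle", rep)))
})
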