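# Deterministic generators for synthetic test inputs: endpoint geometry
# pairs with known internal coordinates, a matched toy force field, and
# seeded rigid-motion/noise perturbations.

.fixture_templates <- c("diatomic", "bent-triatomic", "linear-triatomic",
                        "four-atom-torsion", "butane-like", "two-fragment")

# idealized bond lengths (Angstrom) used by the templates
.ideal_lengths <- c(CC = 1.54, CH = 1.09, OH = 0.96, HH = 0.74, CO = 1.43)

#' Specification of a synthetic fixture geometry
#'
#' @param template one of `"diatomic"`, `"bent-triatomic"`,
#'   `"linear-triatomic"`, `"four-atom-torsion"`, `"butane-like"`,
#'   `"two-fragment"`.
#' @param ... geometric parameters overriding the template defaults:
#'   `r` (bond length, Angstrom), `angle` (degrees), `torsion` (degrees),
#'   `separation` (two-fragment gap, Angstrom).
#' @param seed RNG seed recorded with the spec (construction itself is
#'   deterministic; the seed drives [perturb()]).
#' @return an `fsm_fixture_spec`.
#' @export
fixture_spec <- function(template, ..., seed = 1L) {
  template <- match.arg(template, .fixture_templates)
  structure(list(template = template, params = list(...), seed = seed),
            class = "fsm_fixture_spec")
}

# NERF-style placement: position of a new atom bonded to a, with angle
# theta to b and dihedral phi about the c-b-a axis (radians)
place_atom <- function(a, b, cc, r, theta, phi) {
  bc <- a - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - cc; ab <- ab / sqrt(sum(ab^2))
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  a + d[1L] * bc + d[2L] * m + d[3L] * n
}

#' Build the geometry a fixture spec describes
#'
#' Z-matrix-style construction from the declared internal-coordinate
#' values; re-measuring the built geometry reproduces those values to
#' near machine precision.
#'
#' @param spec an [fixture_spec()].
#' @return a [geometry()].
#' @export
build_fixture <- function(spec) {
  stopifnot(inherits(spec, "fsm_fixture_spec"))
  p <- spec$params
  deg <- function(x) x * pi / 180
  switch(spec$template,
    "diatomic" = {
      r <- p$r %||% .ideal_lengths[["HH"]]
      geometry(c("H", "H"), rbind(c(0, 0, 0), c(r, 0, 0)))
    },
    "bent-triatomic" = {
      r <- p$r %||% .ideal_lengths[["OH"]]
      ang <- deg(p$angle %||% 104.5)
      geometry(c("O", "H", "H"),
               rbind(c(0, 0, 0), c(r, 0, 0),
                     c(r * cos(ang), r * sin(ang), 0)))
    },
    "linear-triatomic" = {
      r <- p$r %||% 1.16
      ang <- deg(p$angle %||% 180)
      geometry(c("O", "C", "O"),
               rbind(c(-r, 0, 0), c(0, 0, 0),
                     c(-r * cos(ang), r * sin(ang), 0)))
    },
    "four-atom-torsion" = ,
    "butane-like" = {
      r <- p$r %||% .ideal_lengths[["CC"]]
      ang <- deg(p$angle %||% 111)
      tor <- deg(p$torsion %||% 180)
      x1 <- c(0, 0, 0); x2 <- c(r, 0, 0)
      x3 <- place_atom(x2, x1, c(0, -1, 0), r, ang, 0)
      x4 <- place_atom(x3, x2, x1, r, ang, tor)
      geometry(c("C", "C", "C", "C"), rbind(x1, x2, x3, x4))
    },
    "two-fragment" = {
      r <- p$r %||% .ideal_lengths[["HH"]]
      sep <- p$separation %||% 5
      geometry(c("H", "H", "H", "H"),
               rbind(c(0, 0, 0), c(r, 0, 0),
                     c(r + sep, 0, 0), c(2 * r + sep, 0, 0)))
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a reactant/product fixture pair
#'
#' Both geometries are built by Z-matrix-style construction from their
#' declared internal coordinates and share atom ordering; construction is
#' deterministic.
#'
#' @param spec_reactant,spec_product [fixture_spec()] objects with the
#'   same template.
#' @return list with `reactant` and `product` geometries.
#' @export
make_pair <- function(spec_reactant, spec_product) {
  if (spec_reactant$template != spec_product$template)
    stop("fixture pair must share a template")
  list(reactant = build_fixture(spec_reactant),
       product = build_fixture(spec_product))
}

#' Matched toy force field for the butane-like template
#'
#' Morse bonds and harmonic angles centered on the template's idealized
#' values (r0 = 1.54 Angstrom, theta0 = 111 degrees) plus a threefold
#' cosine torsion `V/2 (1 + cos(3 phi))` with minima at 60, 180 and 300
#' degrees, so the anti and gauche template endpoints are near-minima of
#' the force field.
#'
#' @param V torsional barrier (surface units; default 5).
#' @param repulsion nonbonded soft-repulsion parameters, or `NULL`.
#' @return a [toyff_spec()].
#' @export
butane_toyff <- function(V = 5, repulsion = list(eps = 0.01, sigma = 1.8)) {
  toyff_spec(
    bonds = data.frame(i = 1:3, j = 2:4, D = 80, a = 2, r0 = 1.54),
    angles = data.frame(i = 1:2, j = 2:3, k = 3:4, kf = 50,
                        theta0 = 111 * pi / 180),
    torsions = data.frame(i = 1, j = 2, k = 3, l = 4, V = V, n = 3, gamma = 0),
    repulsion = repulsion
  )
}

# run fn with a private, restored RNG stream seeded by seed
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# uniform random proper rotation from a normalized quaternion
random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Seeded rigid-motion and/or noise perturbation of a geometry
#'
#' Applies a random proper rotation plus translation (when `rigid`) and
#' then optional isotropic Gaussian coordinate noise. All randomness runs
#' through one seeded generator, so identical seeds reproduce identical
#' output without disturbing the caller's RNG state.
#'
#' @param geom a [geometry()].
#' @param rigid apply a random rotation + translation (default TRUE).
#' @param noise_sigma per-coordinate Gaussian noise, Angstrom (>= 0).
#' @param seed RNG seed.
#' @return the perturbed [geometry()].
#' @export
perturb <- function(geom, rigid = TRUE, noise_sigma = 0, seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  with_seed(seed, function() {
    X <- geom$coords
    if (rigid) {
      R <- random_rotation()
      tr <- stats::runif(3L, -3, 3)
      X <- sweep(X %*% t(R), 2L, tr, FUN = "+")
    }
    if (noise_sigma > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = noise_sigma), nrow(X), 3L)
    with_coords(geom, as.numeric(t(X)))
  })
}
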