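# Primitive internal coordinates: values and exact analytic first
# derivatives (Wilson B-matrix rows) with respect to Cartesians.
#
# Kinds:
#   bond / distance   2 atoms   value in Angstrom
#   angle             3 atoms   radians, [0, pi]
#   linear_bend       3 atoms   radian-like projection onto a stored axis;
#                               two members (axis_tag 1, 2) replace one
#                               near-linear angle
#   torsion           4 atoms   radians, (-pi, pi], periodic
#   out_of_plane      4 atoms   Wilson-style pyramidalization angle at a
#                               trivalent center (2nd atom), [-pi/2, pi/2]

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.prim_kinds <- c("bond", "distance", "angle", "linear_bend", "torsion",
                 "out_of_plane")
.prim_arity <- c(bond = 2L, distance = 2L, angle = 3L, linear_bend = 3L,
                 torsion = 4L, out_of_plane = 4L)

#' Construct a primitive internal coordinate
#'
#' @param kind one of `"bond"`, `"distance"`, `"angle"`, `"linear_bend"`,
#'   `"torsion"`, `"out_of_plane"`.
#' @param atoms 1-based atom indices; length must match the kind (2 for
#'   bond/distance, 3 for angle/linear bend, 4 for torsion/out-of-plane).
#' @param axis for linear bends: the fixed unit bending axis (3-vector).
#' @param axis_tag for linear bends: which of the two orthogonal bending
#'   directions this member represents (1 or 2).
#' @return object of class `fsm_primitive`.
#' @export
primitive <- function(kind, atoms, axis = NULL, axis_tag = NULL) {
  kind <- match.arg(kind, .prim_kinds)
  atoms <- as.integer(atoms)
  if (length(atoms) != .prim_arity[[kind]])
    stop(kind, " takes ", .prim_arity[[kind]], " atoms")
  if (anyDuplicated(atoms)) stop("atom indices must be distinct")
  if (kind == "linear_bend") {
    if (is.null(axis) || length(axis) != 3L)
      stop("linear_bend requires a 3-vector axis")
    axis <- axis / sqrt(sum(axis^2))
  }
  structure(list(kind = kind, atoms = atoms, axis = axis,
                 axis_tag = axis_tag),
            class = "fsm_primitive")
}

#' @export
format.fsm_primitive <- function(x, ...) {
  tag <- if (!is.null(x$axis_tag)) paste0("#", x$axis_tag) else ""
  sprintf("%s%s(%s)", x$kind, tag, paste(x$atoms, collapse = "-"))
}

#' @export
print.fsm_primitive <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

is_periodic_primitive <- function(prim) prim$kind == "torsion"

# canonical identity key used for the reactant/product union
primitive_key <- function(prim) {
  a <- prim$atoms
  a <- switch(prim$kind,
    bond = , distance = sort(a),
    angle = , linear_bend = if (a[1L] > a[3L]) a[3:1] else a,
    torsion = if (a[1L] > a[4L]) a[4:1] else a,
    out_of_plane = c(a[2L], a[1L], sort(a[c(3L, 4L)]))
  )
  key_kind <- if (prim$kind %in% c("bond", "distance")) "pair" else prim$kind
  tag <- if (!is.null(prim$axis_tag)) prim$axis_tag else ""
  paste0(key_kind, ":", paste(a, collapse = ","), ":", tag)
}

# wrap an angle difference onto the shortest signed arc (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y <= -pi, y + 2 * pi, y)
}

#' Measure primitive internal coordinates
#'
#' @param geom a [geometry()].
#' @param primitives a single [primitive()] or a list of them.
#' @return numeric vector of values (Angstrom for bonds/distances, radians
#'   otherwise; torsions in (-pi, pi]).
#' @export
measure_primitives <- function(geom, primitives) {
  if (inherits(primitives, "fsm_primitive")) primitives <- list(primitives)
  vapply(primitives, function(p) measure_one(geom, p), numeric(1L))
}

measure_one <- function(geom, prim, quiet = FALSE) {
  X <- geom$coords
  a <- prim$atoms
  fail <- function(msg) {
    if (quiet) return(NA_real_)
    stop("primitive ", format(prim), ": ", msg)
  }
  switch(prim$kind,
    bond = , distance = sqrt(sum((X[a[2L], ] - X[a[1L], ])^2)),
    angle = {
      u <- X[a[1L], ] - X[a[2L], ]; v <- X[a[3L], ] - X[a[2L], ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) return(fail("coincident atoms"))
      acos(max(-1, min(1, sum(u * v) / (nu * nv))))
    },
    linear_bend = {
      u <- X[a[1L], ] - X[a[2L], ]; v <- X[a[3L], ] - X[a[2L], ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) return(fail("coincident atoms"))
      sum(prim$axis * (u / nu + v / nv))
    },
    torsion = {
      b1 <- X[a[2L], ] - X[a[1L], ]
      b2 <- X[a[3L], ] - X[a[2L], ]
      b3 <- X[a[4L], ] - X[a[3L], ]
      n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
      nb2 <- sqrt(sum(b2^2))
      if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20 || nb2 == 0)
        return(fail("collinear internal atoms: torsion undefined"))
      atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
    },
    out_of_plane = {
      # atoms (A, B, C, D), B trivalent center; chi = asin((e2 x e3) . e1)
      e1 <- X[a[1L], ] - X[a[2L], ]
      e2 <- X[a[3L], ] - X[a[2L], ]
      e3 <- X[a[4L], ] - X[a[2L], ]
      r <- c(sqrt(sum(e1^2)), sqrt(sum(e2^2)), sqrt(sum(e3^2)))
      if (any(r == 0)) return(fail("coincident atoms"))
      d <- sum(cross3(e2 / r[2L], e3 / r[3L]) * (e1 / r[1L]))
      asin(max(-1, min(1, d)))
    }
  )
}

# analytic gradient of one primitive w.r.t. all 3N Cartesians
b_row_one <- function(geom, prim) {
  X <- geom$coords
  n3 <- geom$natoms * 3L
  a <- prim$atoms
  row <- numeric(n3)
  put <- function(row, atom, g3) {
    idx <- (atom - 1L) * 3L + 1:3
    row[idx] <- row[idx] + g3
    row
  }
  switch(prim$kind,
    bond = , distance = {
      d <- X[a[2L], ] - X[a[1L], ]
      r <- sqrt(sum(d^2))
      u <- d / r
      row <- put(row, a[1L], -u)
      row <- put(row, a[2L], u)
      row
    },
    angle = {
      u <- X[a[1L], ] - X[a[2L], ]; v <- X[a[3L], ] - X[a[2L], ]
      ru <- sqrt(sum(u^2)); rv <- sqrt(sum(v^2))
      uh <- u / ru; vh <- v / rv
      ct <- max(-1, min(1, sum(uh * vh)))
      st <- sqrt(max(1 - ct^2, 1e-24))
      ga <- (ct * uh - vh) / (ru * st)
      gc <- (ct * vh - uh) / (rv * st)
      row <- put(row, a[1L], ga)
      row <- put(row, a[3L], gc)
      row <- put(row, a[2L], -(ga + gc))
      row
    },
    linear_bend = {
      u <- X[a[1L], ] - X[a[2L], ]; v <- X[a[3L], ] - X[a[2L], ]
      ru <- sqrt(sum(u^2)); rv <- sqrt(sum(v^2))
      uh <- u / ru; vh <- v / rv
      w <- prim$axis
      ga <- (w - sum(w * uh) * uh) / ru   # d(w.uhat)/dA
      gc <- (w - sum(w * vh) * vh) / rv   # d(w.vhat)/dC
      row <- put(row, a[1L], ga)
      row <- put(row, a[3L], gc)
      row <- put(row, a[2L], -(ga + gc))
      row
    },
    torsion = {
      b1 <- X[a[2L], ] - X[a[1L], ]
      b2 <- X[a[3L], ] - X[a[2L], ]
      b3 <- X[a[4L], ] - X[a[3L], ]
      n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
      nb2 <- sqrt(sum(b2^2))
      sn1 <- sum(n1^2); sn2 <- sum(n2^2)
      if (sn1 < 1e-20 || sn2 < 1e-20)
        stop("primitive ", format(prim), ": collinear internal atoms")
      gA <- -nb2 / sn1 * n1
      gD <- nb2 / sn2 * n2
      p <- sum(b1 * b2) / nb2^2
      q <- sum(b3 * b2) / nb2^2
      gB <- -(1 + p) * gA + q * gD
      gC <- p * gA - (1 + q) * gD
      row <- put(row, a[1L], gA)
      row <- put(row, a[2L], gB)
      row <- put(row, a[3L], gC)
      row <- put(row, a[4L], gD)
      row
    },
    out_of_plane = {
      e <- lapply(c(1L, 3L, 4L), function(i) X[a[i], ] - X[a[2L], ])
      r <- vapply(e, function(v) sqrt(sum(v^2)), numeric(1L))
      eh <- Map(`/`, e, r)
      d <- sum(cross3(eh[[2L]], eh[[3L]]) * eh[[1L]])
      d <- max(-1, min(1, d))
      # d/dehat_k of det[e1h e2h e3h]: cross of the other two, cyclic
      dd <- list(cross3(eh[[2L]], eh[[3L]]),
                 cross3(eh[[3L]], eh[[1L]]),
                 cross3(eh[[1L]], eh[[2L]]))
      pref <- 1 / sqrt(max(1 - d^2, 1e-24))   # d asin
      gs <- vector("list", 3L)
      for (k in 1:3) {
        # chain through unit vector: (I - ehat ehat^T)/r
        gk <- (dd[[k]] - sum(dd[[k]] * eh[[k]]) * eh[[k]]) / r[k]
        gs[[k]] <- pref * gk
      }
      row <- put(row, a[1L], gs[[1L]])
      row <- put(row, a[3L], gs[[2L]])
      row <- put(row, a[4L], gs[[3L]])
      row <- put(row, a[2L], -(gs[[1L]] + gs[[2L]] + gs[[3L]]))
      row
    }
  )
}

#' Wilson B-matrix of a primitive set
#'
#' Row i is the exact analytic gradient of primitive i with respect to all
#' 3N Cartesian coordinates, so that `dq = B dx` for small displacements.
#'
#' @param geom a [geometry()].
#' @param primitives list of [primitive()] objects.
#' @return numeric matrix, `n_primitives x 3N`.
#' @export
wilson_b_matrix <- function(geom, primitives) {
  if (inherits(primitives, "fsm_primitive")) primitives <- list(primitives)
  B <- t(vapply(primitives, function(p) b_row_one(geom, p),
                numeric(geom$natoms * 3L)))
  if (length(primitives) == 1L) B <- matrix(B, nrow = 1L)
  B
}
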