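#' Molecular geometry container
#'
#' A geometry is an ordered set of element symbols plus Cartesian
#' coordinates in Angstrom. Coordinates are stored as an `natoms x 3`
#' matrix; helpers convert to/from the flattened 3N vector used by the
#' string machinery.
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric `natoms x 3` matrix, or a length-`3*natoms` vector
#'   (row-major per atom: x1, y1, z1, x2, ...), in Angstrom.
#' @return an object of class `fsm_geometry` with fields `symbols`,
#'   `coords` (matrix) and `natoms`.
#' @examples
#' g <- geometry(c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' g$natoms
#' @export
geometry <- function(symbols, coords) {
  symbols <- as.character(symbols)
  n <- length(symbols)
  if (n < 1L) stop("geometry needs at least one atom")
  if (is.matrix(coords)) {
    if (nrow(coords) != n || ncol(coords) != 3L)
      stop("coords must be an natoms x 3 matrix")
  } else {
    if (length(coords) != 3L * n)
      stop("coords vector must have length 3 * natoms")
    coords <- matrix(coords, ncol = 3L, byrow = TRUE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  covalent_radius(symbols)  # errors early on unknown elements
  structure(
    list(symbols = symbols, coords = unname(coords), natoms = n),
    class = "fsm_geometry"
  )
}

#' @export
print.fsm_geometry <- function(x, ...) {
  cat(sprintf("<fsm_geometry: %d atoms (%s)>\n", x$natoms,
              paste(x$symbols, collapse = " ")))
  invisible(x)
}

# flattened 3N coordinate vector (x1,y1,z1,x2,...)
coords_vector <- function(geom) as.numeric(t(geom$coords))

# rebuild a geometry from a flattened 3N vector, keeping symbols
with_coords <- function(geom, xvec) {
  geom$coords <- matrix(xvec, ncol = 3L, byrow = TRUE)
  geom
}

same_composition <- function(a, b) {
  a$natoms == b$natoms && all(a$symbols == b$symbols)
}

check_same_composition <- function(a, b) {
  if (!same_composition(a, b))
    stop("geometries must share atom count and element ordering")
  invisible(TRUE)
}

#' Ordered chain of geometries with arc-length parameterization
#'
#' A path holds an ordered list of geometries sharing atom count and
#' element ordering, together with cumulative arc-length values. Arc length
#' is the plain Euclidean norm of the 3N-coordinate displacement between
#' consecutive nodes, unweighted.
#'
#' @param nodes list of [geometry()] objects with identical symbols.
#' @return an object of class `fsm_path` with fields `nodes` and `arc`
#'   (cumulative arc length, Angstrom, starting at 0).
#' @seealso [arc_length()], [spline_tangent()]
#' @export
fsm_path <- function(nodes) {
  if (length(nodes) < 1L) stop("path needs at least one node")
  ref <- nodes[[1L]]
  for (nd in nodes) check_same_composition(ref, nd)
  p <- structure(list(nodes = nodes, arc = NULL), class = "fsm_path")
  p$arc <- arc_length(p)
  p
}

#' @export
print.fsm_path <- function(x, ...) {
  cat(sprintf("<fsm_path: %d nodes, %d atoms, arc length %.4f A>\n",
              length(x$nodes), x$nodes[[1L]]$natoms, max(x$arc)))
  invisible(x)
}

#' Cumulative arc length of a path
#'
#' Arc values start at 0; each increment is the Euclidean norm of the full
#' 3N Cartesian displacement between consecutive nodes (no mass weighting).
#'
#' @param path an [fsm_path()] (a bare list of geometries is also accepted).
#' @return numeric vector of cumulative arc-length values in Angstrom.
#' @export
arc_length <- function(path) {
  nodes <- if (inherits(path, "fsm_path")) path$nodes else path
  ref <- nodes[[1L]]
  arc <- numeric(length(nodes))
  if (length(nodes) >= 2L) {
    prev <- coords_vector(ref)
    for (i in 2:length(nodes)) {
      check_same_composition(ref, nodes[[i]])
      cur <- coords_vector(nodes[[i]])
      arc[i] <- arc[i - 1L] + sqrt(sum((cur - prev)^2))
      prev <- cur
    }
  }
  arc
}

#' Rigid-body superposition by the Kabsch algorithm
#'
#' Rotates and translates `mobile` onto `reference` so as to minimize the
#' root-mean-square deviation, with the usual determinant guard so only
#' proper rotations (no reflections) are applied.
#'
#' @param reference,mobile geometries with identical symbols and ordering.
#' @return list with `geometry` (the aligned copy of `mobile`), `rmsd`
#'   (Angstrom), and `rotation` (the 3x3 proper rotation applied).
#' @examples
#' g <- geometry(c("O", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
#' kabsch_align(g, g)$rmsd
#' @export
kabsch_align <- function(reference, mobile) {
  check_same_composition(reference, mobile)
  P <- mobile$coords
  Q <- reference$coords
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp)
  Q0 <- sweep(Q, 2L, cq)
  H <- crossprod(P0, Q0)              # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)         # proper rotation: det(R) = +1
  aligned <- sweep(P0 %*% t(R), 2L, cq, FUN = "+")
  rmsd <- sqrt(sum((aligned - Q)^2) / reference$natoms)
  list(geometry = with_coords(mobile, as.numeric(t(aligned))),
       rmsd = rmsd, rotation = R)
}

# componentwise natural cubic splines of all 3N coordinates against arc
# length; returns a function(arc_value, deriv) -> 3N vector
path_spline <- function(path) {
  arc <- path$arc
  if (diff(range(arc)) <= 0)
    stop("degenerate path: all arc-length values are equal")
  X <- t(vapply(path$nodes, coords_vector, numeric(path$nodes[[1L]]$natoms * 3L)))
  if (length(path$nodes) == 2L) {
    # straight-line secant fallback for 2-node paths
    dir <- (X[2L, ] - X[1L, ]) / (arc[2L] - arc[1L])
    return(function(s, deriv = 0L) {
      if (deriv == 0L) X[1L, ] + (s - arc[1L]) * dir else dir
    })
  }
  fns <- lapply(seq_len(ncol(X)), function(j)
    stats::splinefun(arc, X[, j], method = "natural"))
  function(s, deriv = 0L) vapply(fns, function(f) f(s, deriv = deriv), numeric(1L))
}

# unit tangent of the componentwise cubic spline at an arbitrary arc value
tangent_at_arc <- function(path, s) {
  sp <- path_spline(path)
  t <- sp(s, deriv = 1L)
  nt <- sqrt(sum(t^2))
  if (nt == 0) stop("zero spline derivative: tangent undefined")
  t / nt
}

#' Unit path tangent from a cubic spline fit
#'
#' Each of the 3N Cartesian coordinates is fitted with a natural cubic
#' spline against cumulative arc length; the tangent at a node is the
#' normalized derivative of that spline evaluated at the node's arc value.
#' Two-node paths fall back to the straight-line secant direction.
#'
#' @param path an [fsm_path()] with at least 2 nodes.
#' @param node_index 1-based node index.
#' @return unit-norm numeric vector of length 3N.
#' @export
spline_tangent <- function(path, node_index) {
  if (!inherits(path, "fsm_path")) path <- fsm_path(path)
  n <- length(path$nodes)
  if (n < 2L) stop("path needs at least 2 nodes for a tangent")
  if (node_index < 1L || node_index > n) stop("node_index out of range")
  tangent_at_arc(path, path$arc[node_index])
}
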