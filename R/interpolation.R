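# Chain-of-states interpolation between two frontier geometries: linear
# interpolation in redundant internal coordinates with iterative
# back-transformation, or linear synchronous transit (LST) least-squares
# interpolation in internuclear distances.

new_interpolation_result <- function(path, fractions, diagnostics) {
  structure(list(path = path, fractions = fractions,
                 diagnostics = diagnostics),
            class = "fsm_interpolation")
}

#' @export
print.fsm_interpolation <- function(x, ...) {
  cat(sprintf("<fsm_interpolation: %d nodes, arc length %.4f A>\n",
              length(x$path$nodes), max(x$path$arc)))
  invisible(x)
}

#' Linear interpolation in redundant internal coordinates
#'
#' Targets `q(f) = (1 - f) q_R + f q_P` on a uniform grid of `nfractions`
#' values of f in `[0, 1]`, with torsions interpolated along the shortest
#' signed arc, each converted to Cartesians by [cartesian_from_internal()]
#' seeded from the previously converted node (the left endpoint seeds the
#' first interior node). The input endpoints are kept bit-exact.
#'
#' @param left,right frontier geometries (shared symbols/ordering).
#' @param icsys an `fsm_icsystem` from [build_ic_system()].
#' @param nfractions number of nodes including both endpoints (>= 2).
#' @return an `fsm_interpolation`: `path`, `fractions`, and a
#'   `diagnostics` data frame (per-node convergence flag, iterations,
#'   residual).
#' @export
ric_interpolate <- function(left, right, icsys, nfractions = 21L) {
  check_same_composition(left, right)
  if (nfractions < 2L) stop("nfractions must be >= 2")
  prims <- icsys$primitives
  qL <- measure_primitives(left, prims)
  qR <- measure_primitives(right, prims)
  dq <- primitive_difference(prims, qR, qL)  # shortest-arc for torsions
  f <- seq(0, 1, length.out = nfractions)
  nodes <- vector("list", nfractions)
  nodes[[1L]] <- left
  nodes[[nfractions]] <- right
  diag <- data.frame(f = f, converged = TRUE, iterations = 0L, residual = 0)
  if (nfractions > 2L) {
    seed <- left
    for (k in 2:(nfractions - 1L)) {
      target <- qL + f[k] * dq
      g <- tryCatch(cartesian_from_internal(target, seed, icsys),
                    error = function(e) {
                      cond <- simpleError(paste0(
                        "RIC back-transformation failed at f = ", signif(f[k], 4),
                        ": ", conditionMessage(e)))
                      cond$partial <- nodes[!vapply(nodes, is.null, logical(1L))]
                      stop(cond)
                    })
      diag$converged[k] <- isTRUE(attr(g, "converged"))
      diag$iterations[k] <- attr(g, "iterations")
      diag$residual[k] <- attr(g, "residual")
      attributes(g)[c("converged", "iterations", "residual")] <- NULL
      nodes[[k]] <- g
      seed <- g
    }
  }
  new_interpolation_result(fsm_path(nodes), f, diag)
}

# all N(N-1)/2 internuclear distances, fixed (i < j) order
pair_distances <- function(X) {
  d <- stats::dist(X)
  as.numeric(d)
}

# S^LST objective and its analytic gradient at flattened coords x
lst_objective <- function(xvec, r_i, x_i, w, floor4) {
  X <- matrix(xvec, ncol = 3L, byrow = TRUE)
  n <- nrow(X)
  e <- w * sum((xvec - x_i)^2)
  grad <- 2 * w * (xvec - x_i)
  if (n >= 2L) {
    # stats::dist enumerates pairs (1,2),(1,3),...,(1,n),(2,3),...; mirror it
    k <- 0L
    for (ii in 1:(n - 1L)) for (jj in (ii + 1L):n) {
      k <- k + 1L
      dvec <- X[jj, ] - X[ii, ]
      rc <- sqrt(sum(dvec^2))
      denom <- max(r_i[k]^4, floor4)
      e <- e + (r_i[k] - rc)^2 / denom
      dEdr <- -2 * (r_i[k] - rc) / denom
      u <- dvec / rc
      gi <- -dEdr * u
      idx_i <- (ii - 1L) * 3L + 1:3
      idx_j <- (jj - 1L) * 3L + 1:3
      grad[idx_i] <- grad[idx_i] + gi
      grad[idx_j] <- grad[idx_j] - gi
    }
  }
  list(value = e, gradient = grad)
}

#' Linear synchronous transit (LST) interpolation
#'
#' For each interpolation fraction f, target internuclear distances
#' `r(f) = (1 - f) r_R + f r_P` and Cartesian interpolants
#' `x(f) = (1 - f) x_R + f x_P` are formed, and the node coordinates
#' minimize the least-squares objective
#' `S = sum_{a>b} (r_ab(f) - r_ab)^2 / r_ab(f)^4 + w sum_j (x_j(f) - x_j)^2`
#' via bounded quasi-Newton (L-BFGS-B) started from the Cartesian
#' interpolant. The small weight `w` suppresses rigid translation and
#' rotation of the nodes relative to the endpoints. The denominator is
#' floored at `(0.5 A)^4` to guard near-coincident interpolated
#' distances. For single-atom systems the distance sum is empty and the
#' method reduces to Cartesian linear interpolation.
#'
#' @param left,right frontier geometries.
#' @param nfractions number of nodes including both endpoints (>= 2).
#' @param w Cartesian regularization weight (nominally 1e-6).
#' @param maxit minimizer iteration cap per node.
#' @param pgtol projected-gradient max-norm convergence threshold.
#' @return an `fsm_interpolation`; `diagnostics` records each node's
#'   objective at the start point and after minimization.
#' @export
lst_interpolate <- function(left, right, nfractions = 21L, w = 1e-6,
                            maxit = 500L, pgtol = 1e-8) {
  check_same_composition(left, right)
  if (nfractions < 2L) stop("nfractions must be >= 2")
  xL <- coords_vector(left); xR <- coords_vector(right)
  rL <- pair_distances(left$coords); rR <- pair_distances(right$coords)
  f <- seq(0, 1, length.out = nfractions)
  floor4 <- 0.5^4
  nodes <- vector("list", nfractions)
  nodes[[1L]] <- left
  nodes[[nfractions]] <- right
  diag <- data.frame(f = f, s_start = 0, s_final = 0, converged = TRUE)
  if (nfractions > 2L) {
    for (k in 2:(nfractions - 1L)) {
      r_i <- (1 - f[k]) * rL + f[k] * rR
      x_i <- (1 - f[k]) * xL + f[k] * xR
      s0 <- lst_objective(x_i, r_i, x_i, w, floor4)$value
      if (left$natoms == 1L) {
        nodes[[k]] <- with_coords(left, x_i)
        diag$s_start[k] <- s0; diag$s_final[k] <- s0
        next
      }
      opt <- stats::optim(
        par = x_i,
        fn = function(x) lst_objective(x, r_i, x_i, w, floor4)$value,
        gr = function(x) lst_objective(x, r_i, x_i, w, floor4)$gradient,
        method = "L-BFGS-B",
        control = list(maxit = maxit, pgtol = pgtol, factr = 10))
      if (!opt$convergence %in% c(0L, 1L)) {
        cond <- simpleError(paste0("LST minimizer failed at node ", k, " (f = ",
                                   signif(f[k], 4), "): ", opt$message))
        cond$node <- k; cond$residual <- opt$value
        stop(cond)
      }
      # the minimizer must never worsen the start point
      if (opt$value > s0) opt <- list(par = x_i, value = s0, convergence = 0L)
      nodes[[k]] <- with_coords(left, opt$par)
      diag$s_start[k] <- s0
      diag$s_final[k] <- opt$value
      diag$converged[k] <- opt$convergence == 0L
    }
  }
  new_interpolation_result(fsm_path(nodes), f, diag)
}

#' Walk a fixed arc distance along an interpolated path
#'
#' Locates the point at arc distance `s` from the chosen end of a dense
#' interpolated path by monotone linear interpolation of the path's
#' arc-length parameterization between bracketing nodes.
#'
#' @param interp an `fsm_interpolation` (or an [fsm_path()]).
#' @param from_left walk from the first node (`TRUE`) or last (`FALSE`).
#' @param s arc distance in Angstrom; must be smaller than the total arc
#'   length, otherwise the strings-meet condition is signalled.
#' @return a [geometry()] at the requested arc position.
#' @export
take_step <- function(interp, from_left = TRUE, s) {
  path <- if (inherits(interp, "fsm_interpolation")) interp$path else interp
  arc <- path$arc
  total <- max(arc)
  if (s >= total) {
    cond <- simpleCondition("step exceeds path length: strings meet",
                            call = sys.call())
    class(cond) <- c("fsm_strings_meet", "error", "condition")
    stop(cond)
  }
  target <- if (from_left) s else total - s
  if (s == 0) return(path$nodes[[if (from_left) 1L else length(path$nodes)]])
  j <- max(which(arc <= target))
  if (j == length(arc)) return(path$nodes[[j]])
  t <- (target - arc[j]) / (arc[j + 1L] - arc[j])
  xa <- coords_vector(path$nodes[[j]])
  xb <- coords_vector(path$nodes[[j + 1L]])
  with_coords(path$nodes[[j]], (1 - t) * xa + t * xb)
}

#' Write per-node interpolation diagnostics as TSV
#'
#' @param interp an `fsm_interpolation`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_interpolation_diagnostics <- function(interp, file) {
  d <- interp$diagnostics
  d$arc <- interp$path$arc
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
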