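# Redundant internal coordinate systems: detection, pruning of the
# reactant/product union, delocalization via G = B B^T, and iterative
# back-transformation of internal targets to Cartesians.

NEAR_LINEAR_DEG <- 175     # bond/torsion angles beyond this are "linear"
LINEAR_BEND_PRUNE_DEG <- 135  # linear bend dropped when angle < this
BOND_SCALE_DEFAULT <- 1.3     # r < scale * (rcov_a + rcov_b) is a bond

deg2rad <- function(x) x * pi / 180

# bond adjacency from the covalent-radius criterion; disconnected
# fragments are joined by the single shortest inter-fragment pair, which
# also enters the connectivity graph so angles/torsions span fragments
bond_graph <- function(geom, bond_scale = BOND_SCALE_DEFAULT) {
  n <- geom$natoms
  rc <- covalent_radius(geom$symbols)
  D <- as.matrix(stats::dist(geom$coords))
  adj <- matrix(FALSE, n, n)
  bonds <- list(); connectors <- list()
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (D[i, j] < bond_scale * (rc[i] + rc[j])) {
        adj[i, j] <- adj[j, i] <- TRUE
        bonds[[length(bonds) + 1L]] <- c(i, j)
      }
    }
  }
  # connected components by BFS
  comp <- integer(n); cc <- 0L
  for (s in 1:n) {
    if (comp[s] != 0L) next
    cc <- cc + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cc
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  while (max(comp) > 1L) {
    # join the globally closest pair of distinct fragments, repeat
    best <- NULL; bd <- Inf
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (comp[i] != comp[j] && D[i, j] < bd) { bd <- D[i, j]; best <- c(i, j) }
    }
    adj[best[1L], best[2L]] <- adj[best[2L], best[1L]] <- TRUE
    connectors[[length(connectors) + 1L]] <- best
    comp[comp == comp[best[2L]]] <- comp[best[1L]]
    comp <- match(comp, sort(unique(comp)))
  }
  list(adj = adj, bonds = bonds, connectors = connectors)
}

#' Detect primitive internal coordinates of a geometry
#'
#' Bonds come from a covalent-radius criterion (`r < bond_scale *
#' (rcov_a + rcov_b)`); when the resulting graph is disconnected, the
#' shortest inter-fragment atom pair is added as an auxiliary `distance`
#' coordinate (and as a graph edge) until the graph is connected. Angles
#' are generated for every bonded A-B-C, torsions for every bonded
#' A-B-C-D path, and one out-of-plane coordinate at every trivalent
#' center.
#'
#' @param geom a [geometry()] with at least 2 atoms.
#' @param bond_scale multiplier on the covalent-radius sum (default 1.3).
#' @return ordered list of [primitive()] objects (deterministic for
#'   identical inputs).
#' @export
detect_primitives <- function(geom, bond_scale = BOND_SCALE_DEFAULT) {
  n <- geom$natoms
  if (n < 2L) stop("primitive detection needs at least 2 atoms")
  bg <- bond_graph(geom, bond_scale)
  adj <- bg$adj
  prims <- list()
  add <- function(p) prims[[length(prims) + 1L]] <<- p
  for (b in bg$bonds) add(primitive("bond", b))
  for (d in bg$connectors) add(primitive("distance", d))
  nbrs <- lapply(1:n, function(i) which(adj[i, ]))
  # angles: every bonded A-B-C, A < C for determinism
  for (b in 1:n) {
    nb <- nbrs[[b]]
    if (length(nb) >= 2L)
      for (ia in 1:(length(nb) - 1L)) for (ic in (ia + 1L):length(nb))
        add(primitive("angle", c(nb[ia], b, nb[ic])))
  }
  # torsions: every bonded path A-B-C-D with B < C for determinism
  for (b in 1:n) for (cc in nbrs[[b]]) {
    if (cc <= b) next
    for (aa in nbrs[[b]]) for (dd in nbrs[[cc]]) {
      if (aa == cc || dd == b || aa == dd) next
      add(primitive("torsion", c(aa, b, cc, dd)))
    }
  }
  # out-of-plane at trivalent centers
  for (b in 1:n) {
    nb <- nbrs[[b]]
    if (length(nb) == 3L)
      add(primitive("out_of_plane", c(nb[1L], b, nb[2L], nb[3L])))
  }
  prims
}

# deterministic sort order for a primitive list
order_primitives <- function(prims) {
  kind_rank <- c(bond = 1L, distance = 2L, linear_bend = 3L, angle = 4L,
                 torsion = 5L, out_of_plane = 6L)
  keys <- vapply(prims, function(p) {
    a <- c(p$atoms, rep(0L, 4L - length(p$atoms)))
    tag <- if (is.null(p$axis_tag)) 0L else p$axis_tag
    sprintf("%02d_%04d_%04d_%04d_%04d_%d", kind_rank[[p$kind]],
            a[1L], a[2L], a[3L], a[4L], tag)
  }, character(1L))
  prims[order(keys)]
}

# two orthogonal bending axes for a near-linear A-B-C, chosen
# deterministically from the reference geometry: axis u is the lab axis
# least parallel to the A->C direction, projected perpendicular to it;
# axis v completes the right-handed frame
linear_bend_axes <- function(refgeom, atoms) {
  X <- refgeom$coords
  w <- X[atoms[3L], ] - X[atoms[1L], ]
  w <- w / sqrt(sum(w^2))
  lab <- diag(3)
  e <- lab[, which.min(abs(w))]
  u <- e - sum(e * w) * w
  u <- u / sqrt(sum(u^2))
  v <- cross3(w, u)
  list(u, v / sqrt(sum(v^2)))
}

#' Build the pruned internal-coordinate system for a reactant/product pair
#'
#' Takes the union of [detect_primitives()] on both endpoint geometries
#' and applies, in order: (a) angles nearly linear (> 175 degrees) in
#' either endpoint are replaced by two orthogonal linear-bend
#' coordinates; (b) a linear-bend pair is pruned when the angle deviates
#' from linearity by more than 45 degrees (angle < 135 degrees) in either
#' endpoint; (c) torsions with |dihedral| > 175 degrees in either
#' endpoint are removed and an A-D distance coordinate is added; (d)
#' torsions containing a near-linear internal bend in either endpoint are
#' removed; (e) out-of-plane coordinates whose center has a near-linear
#' flanking angle, or whose center's bond set differs between the two
#' endpoints (a broken bonding center), are removed; (f) if more than 3
#' atoms and no torsion survives, candidate A,B,C,D quadruples are
#' scanned for a torsion valid in both endpoints; (g) failing that, the
#' whole set is replaced by all unique atom-atom distances. The
#' delocalized basis U is then computed on the reactant geometry.
#'
#' @param reactant,product geometries with identical symbols/ordering.
#' @param bond_scale covalent-radius multiplier for bond detection.
#' @return object of class `fsm_icsystem`: `primitives`, `U`
#'   (n_prim x m orthonormal), `B` (the delocalized B-matrix at the
#'   reactant), `eig_threshold`, and a `prune_log` data frame.
#' @export
build_ic_system <- function(reactant, product, bond_scale = BOND_SCALE_DEFAULT) {
  check_same_composition(reactant, product)
  pr <- detect_primitives(reactant, bond_scale)
  pp <- detect_primitives(product, bond_scale)
  union <- list(); seen <- character(0L)
  for (p in c(pr, pp)) {
    k <- primitive_key(p)
    if (!(k %in% seen)) { seen <- c(seen, k); union[[length(union) + 1L]] <- p }
  }
  union <- order_primitives(union)
  log <- list()
  note <- function(prim, rule, action)
    log[[length(log) + 1L]] <<- data.frame(
      primitive = format(prim), rule = rule, action = action,
      stringsAsFactors = FALSE)

  ang <- function(geom, atoms)
    measure_one(geom, primitive("angle", atoms), quiet = TRUE)
  near_linear <- function(atoms)
    max(ang(reactant, atoms), ang(product, atoms), na.rm = TRUE) >
      deg2rad(NEAR_LINEAR_DEG)

  kept <- list(); extra <- list()
  # (a)/(b): angle handling
  for (p in union) {
    if (p$kind != "angle") { kept[[length(kept) + 1L]] <- p; next }
    if (!near_linear(p$atoms)) { kept[[length(kept) + 1L]] <- p; next }
    note(p, "near_linear_angle", "replaced by two linear bends")
    # reference endpoint for the fixed axes: whichever endpoint is more
    # linear defines the geometry the bends stabilize; ties go reactant
    ref <- if (isTRUE(ang(product, p$atoms) > ang(reactant, p$atoms)))
      product else reactant
    axes <- linear_bend_axes(ref, p$atoms)
    amin <- min(ang(reactant, p$atoms), ang(product, p$atoms), na.rm = TRUE)
    if (amin < deg2rad(LINEAR_BEND_PRUNE_DEG)) {
      note(p, "linear_bend_overbent", "linear-bend pair pruned")
      next
    }
    for (tag in 1:2)
      extra[[length(extra) + 1L]] <-
        primitive("linear_bend", p$atoms, axis = axes[[tag]], axis_tag = tag)
  }
  kept <- c(kept, extra)

  # (c)/(d): torsion handling
  out <- list()
  tor_dist <- list()
  for (p in kept) {
    if (p$kind != "torsion") { out[[length(out) + 1L]] <- p; next }
    a <- p$atoms
    tR <- measure_one(reactant, p, quiet = TRUE)
    tP <- measure_one(product, p, quiet = TRUE)
    if (any(abs(c(tR, tP)) > deg2rad(NEAR_LINEAR_DEG), na.rm = TRUE) ||
        anyNA(c(tR, tP))) {
      note(p, "trans_planar_torsion", "replaced by A-D distance")
      tor_dist[[length(tor_dist) + 1L]] <- primitive("distance", c(a[1L], a[4L]))
      next
    }
    if (near_linear(a[1:3]) || near_linear(a[2:4])) {
      note(p, "linear_internal_bend", "torsion removed")
      next
    }
    out[[length(out) + 1L]] <- p
  }
  kept <- c(out, tor_dist)

  # (e): out-of-plane handling
  adjR <- bond_graph(reactant, bond_scale)$adj
  adjP <- bond_graph(product, bond_scale)$adj
  out <- list()
  for (p in kept) {
    if (p$kind != "out_of_plane") { out[[length(out) + 1L]] <- p; next }
    a <- p$atoms
    center <- a[2L]
    degenerate <- near_linear(c(a[1L], center, a[3L])) ||
      near_linear(c(a[1L], center, a[4L])) ||
      near_linear(c(a[3L], center, a[4L]))
    broken <- !identical(adjR[center, ], adjP[center, ])
    if (degenerate) { note(p, "near_linear_oop", "removed"); next }
    if (broken) { note(p, "broken_bonding_center", "removed"); next }
    out[[length(out) + 1L]] <- p
  }
  kept <- out

  n <- reactant$natoms
  has_torsion <- any(vapply(kept, function(p) p$kind == "torsion", logical(1L)))
  if (n > 3L && !has_torsion) {
    # (f): scan quadruples for a torsion valid in both endpoints
    found <- NULL
    combos <- utils::combn(n, 4L)
    perms <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(2, 1, 3, 4),
                  c(1, 2, 4, 3), c(2, 1, 4, 3), c(3, 1, 2, 4),
                  c(1, 4, 2, 3), c(1, 3, 4, 2), c(2, 3, 1, 4),
                  c(4, 1, 2, 3), c(3, 2, 1, 4), c(2, 4, 1, 3))
    for (ci in seq_len(ncol(combos))) {
      for (pm in perms) {
        a <- combos[pm, ci]
        tp <- primitive("torsion", a)
        tR <- measure_one(reactant, tp, quiet = TRUE)
        tP <- measure_one(product, tp, quiet = TRUE)
        ok <- !anyNA(c(tR, tP)) &&
          all(abs(c(tR, tP)) <= deg2rad(NEAR_LINEAR_DEG)) &&
          !near_linear(a[1:3]) && !near_linear(a[2:4])
        if (ok) { found <- tp; break }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) {
      note(found, "torsion_rescue", "torsion added by permutation scan")
      kept[[length(kept) + 1L]] <- found
    } else {
      # (g): fall back to all unique atom-atom distances
      note(primitive("distance", c(1L, 2L)), "no_valid_torsion",
           "primitive set replaced by all unique atom-atom distances")
      kept <- list()
      for (i in 1:(n - 1L)) for (j in (i + 1L):n)
        kept[[length(kept) + 1L]] <- primitive("distance", c(i, j))
    }
  }

  # dedupe (c) may have added distances that already exist as bonds
  final <- list(); seen <- character(0L)
  for (p in kept) {
    k <- primitive_key(p)
    if (!(k %in% seen)) { seen <- c(seen, k); final[[length(final) + 1L]] <- p }
  }
  final <- order_primitives(final)
  if (length(final) == 0L) stop("no internal coordinates could be constructed")
  # every primitive must be finite at both endpoints
  qR <- vapply(final, function(p) measure_one(reactant, p, quiet = TRUE), numeric(1L))
  qP <- vapply(final, function(p) measure_one(product, p, quiet = TRUE), numeric(1L))
  bad <- !is.finite(qR) | !is.finite(qP)
  if (any(bad)) {
    for (p in final[bad]) note(p, "undefined_at_endpoint", "removed")
    final <- final[!bad]
  }

  dl <- delocalize(wilson_b_matrix(reactant, final), natoms = n)
  structure(list(
    primitives = final,
    U = dl$U, B = dl$B, eig_threshold = dl$eig_threshold,
    prune_log = if (length(log)) do.call(rbind, log) else
      data.frame(primitive = character(), rule = character(),
                 action = character(), stringsAsFactors = FALSE)
  ), class = "fsm_icsystem")
}

#' @export
print.fsm_icsystem <- function(x, ...) {
  kinds <- table(vapply(x$primitives, function(p) p$kind, character(1L)))
  cat(sprintf("<fsm_icsystem: %d primitives (%s), %d delocalized coordinates>\n",
              length(x$primitives),
              paste(names(kinds), kinds, sep = ":", collapse = ", "),
              ncol(x$U)))
  invisible(x)
}

#' Delocalize a primitive B-matrix
#'
#' Diagonalizes `G = B_prim B_prim^T`; eigenvectors with eigenvalue above
#' `threshold_frac` times the largest eigenvalue span the nonredundant
#' (delocalized) subspace U, and the active B-matrix is `B = U^T B_prim`.
#'
#' @param Bprim primitive B-matrix (n_prim x 3N).
#' @param natoms atom count (used only for the sanity cap on the subspace
#'   dimension); optional.
#' @param threshold_frac eigenvalue cutoff as a fraction of the largest
#'   eigenvalue (default 1e-10).
#' @return list with `U` (n_prim x m, orthonormal columns), `B` (m x 3N),
#'   `eigenvalues`, and `eig_threshold`.
#' @export
delocalize <- function(Bprim, natoms = NULL, threshold_frac = 1e-10) {
  if (!is.matrix(Bprim) || nrow(Bprim) < 1L) stop("Bprim must be a nonempty matrix")
  G <- Bprim %*% t(Bprim)
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  thr <- threshold_frac * max(eg$values)
  keep <- eg$values > thr
  if (!any(keep)) stop("degenerate coordinate system: all G eigenvalues below threshold")
  U <- eg$vectors[, keep, drop = FALSE]
  list(U = U, B = t(U) %*% Bprim, eigenvalues = eg$values, eig_threshold = thr)
}

#' Moore-Penrose-style inverse of the delocalized B-matrix
#'
#' Returns `(B B^T)^{-1} B`, the generalized inverse used to convert
#' delocalized internal displacements to Cartesian displacements via
#' `dx = t(b_pseudo_inverse(B)) %*% dq_dlc`.
#'
#' @param B delocalized B-matrix (m x 3N), full row rank.
#' @return m x 3N matrix.
#' @export
b_pseudo_inverse <- function(B) {
  BBt <- B %*% t(B)
  inv <- tryCatch(solve(BBt), error = function(e)
    stop("singular B B^T: cannot form inverse B-matrix"))
  inv %*% B
}

# signed primitive difference target - current, wrapped for torsions
primitive_difference <- function(primitives, q_target, q_current) {
  dq <- q_target - q_current
  per <- vapply(primitives, is_periodic_primitive, logical(1L))
  dq[per] <- wrap_angle(dq[per])
  dq
}

#' Iterative back-transformation from internal targets to Cartesians
#'
#' Solves for Cartesian coordinates whose primitive internal values match
#' `target_q` by iterating
#' `x_{k+1} = x_k + t((B B^T)^{-1} B) (U^T dq)`,
#' recomputing the B-matrix at every iterate. Torsion differences are
#' wrapped onto the shortest signed arc before projection into the
#' delocalized basis. Iteration stops when the largest Cartesian
#' coordinate change is below `tol` (default 1e-7 Angstrom). On
#' non-convergence within `max_iters` the iterate with the smallest
#' residual is returned, flagged approximate.
#'
#' @param target_q target values of `icsys$primitives` (primitive space;
#'   Angstrom/radians).
#' @param start a [geometry()] used as the initial iterate.
#' @param icsys an `fsm_icsystem` from [build_ic_system()].
#' @param tol convergence threshold on the max Cartesian step (Angstrom).
#' @param max_iters iteration cap (default 100).
#' @param step_cap per-coordinate cap on a single update (Angstrom).
#' @return a [geometry()] with attributes `converged` (logical),
#'   `iterations`, and `residual` (Euclidean norm of the remaining
#'   delocalized displacement).
#' @export
cartesian_from_internal <- function(target_q, start, icsys,
                                    tol = 1e-7, max_iters = 100L,
                                    step_cap = 0.5) {
  prims <- icsys$primitives
  if (length(target_q) != length(prims))
    stop("target_q length must match the primitive count")
  U <- icsys$U
  x <- coords_vector(start)
  best <- list(x = x, residual = Inf, iter = 0L)
  grow <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < max_iters) {
    iter <- iter + 1L
    geom <- with_coords(start, x)
    qc <- measure_primitives(geom, prims)
    dq <- primitive_difference(prims, target_q, qc)
    dq_dlc <- as.numeric(t(U) %*% dq)
    residual <- sqrt(sum(dq_dlc^2))
    if (residual < best$residual) {
      best <- list(x = x, residual = residual, iter = iter)
      grow <- 0L
    } else {
      grow <- grow + 1L
      if (grow >= max_iters) {
        cond <- simpleError("back-transformation diverged")
        cond$best <- with_coords(start, best$x)
        stop(cond)
      }
    }
    Bp <- wilson_b_matrix(geom, prims)
    B <- t(U) %*% Bp
    dx <- as.numeric(t(b_pseudo_inverse(B)) %*% dq_dlc)
    dx <- pmin(pmax(dx, -step_cap), step_cap)
    x <- x + dx
    if (max(abs(dx)) < tol) { converged <- TRUE; break }
  }
  out <- with_coords(start, if (converged) x else best$x)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  attr(out, "residual") <- if (converged) {
    qc <- measure_primitives(out, prims)
    sqrt(sum(as.numeric(t(U) %*% primitive_difference(prims, target_q, qc))^2))
  } else best$residual
  out
}

#' Plain-text report of a primitive list
#'
#' One primitive per line: kind, atoms, value at the reactant, value at
#' the product, and any prune-log entries. Intended as a debugging aid.
#'
#' @param icsys an `fsm_icsystem`.
#' @param reactant,product the endpoint geometries.
#' @param file optional output path; when `NULL` the report is returned
#'   as a character vector.
#' @return character vector of report lines (invisibly when written).
#' @export
dump_primitives <- function(icsys, reactant, product, file = NULL) {
  qR <- measure_primitives(reactant, icsys$primitives)
  qP <- measure_primitives(product, icsys$primitives)
  lines <- sprintf("%-28s %12.6f %12.6f",
                   vapply(icsys$primitives, format, character(1L)), qR, qP)
  if (nrow(icsys$prune_log)) {
    lines <- c(lines, "# prune log:",
               sprintf("# %-28s %-22s %s", icsys$prune_log$primitive,
                       icsys$prune_log$rule, icsys$prune_log$action))
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
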