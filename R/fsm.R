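# The freezing string growth loop: frontier placement along an
# interpolated path, cubic-spline tangents, perpendicular-gradient node
# optimization with bounded quasi-Newton steps and backtracking line
# search, freezing, and TS-guess selection.

#' FSM run configuration
#'
#' @param n_nodes nominal node count used to fix the interpolation step
#'   size `s` (arc length of the initial interpolated path divided by
#'   `n_nodes`); default 18.
#' @param n_opt maximum optimization steps per node (default 2; 0 gives
#'   pure interpolation with energies evaluated only for TS-guess
#'   selection).
#' @param n_ls maximum energy/gradient evaluations per line search
#'   (default 3).
#' @param max_disp per-coordinate displacement bound per optimization
#'   step, Angstrom (default 0.3), applied relative to each step's start.
#' @param interpolator `"ric"` (linear interpolation in redundant internal
#'   coordinates) or `"lst"` (linear synchronous transit; reduces to
#'   Cartesian interpolation for single-atom systems).
#' @param grad_tol perpendicular-gradient max-norm convergence threshold
#'   for early termination of a node's optimization.
#' @param join_threshold strings are considered met when the frontier-gap
#'   arc length drops to `join_threshold * s` (default 1.5).
#' @param dense_fractions nodes in each dense interpolated segment used
#'   for arc length, stepping, and tangents (default 21).
#' @param align align product onto reactant with the Kabsch algorithm
#'   before growing (default TRUE; automatically skipped for single-atom
#'   systems, where superposition would collapse the endpoints).
#' @param bond_scale covalent-radius multiplier for bond detection (RIC).
#' @param lst_w LST Cartesian regularization weight.
#' @param seed optional RNG seed recorded in the configuration (the growth
#'   loop itself is deterministic; the seed is plumbing for calculators or
#'   fixtures that use randomness).
#' @return an `fsm_config` list.
#' @export
fsm_config <- function(n_nodes = 18L, n_opt = 2L, n_ls = 3L, max_disp = 0.3,
                       interpolator = c("ric", "lst"), grad_tol = 1e-4,
                       join_threshold = 1.5, dense_fractions = 21L,
                       align = TRUE, bond_scale = BOND_SCALE_DEFAULT,
                       lst_w = 1e-6, seed = NULL) {
  interpolator <- match.arg(interpolator)
  if (n_nodes < 3L) stop("n_nodes must be >= 3")
  if (n_opt < 0L) stop("n_opt must be >= 0")
  if (n_ls < 1L) stop("n_ls must be >= 1")
  if (max_disp <= 0) stop("max_disp must be > 0")
  structure(list(n_nodes = as.integer(n_nodes), n_opt = as.integer(n_opt),
                 n_ls = as.integer(n_ls), max_disp = max_disp,
                 interpolator = interpolator, grad_tol = grad_tol,
                 join_threshold = join_threshold,
                 dense_fractions = as.integer(dense_fractions),
                 align = align, bond_scale = bond_scale, lst_w = lst_w,
                 seed = seed),
            class = "fsm_config")
}

#' Gradient component perpendicular to the path tangent
#'
#' `g_perp = (I - t t^T) g = g - (t . g) t` for a unit tangent `t`.
#'
#' @param g Cartesian gradient (length 3N).
#' @param t unit tangent vector (length 3N).
#' @return the projected gradient; exactly orthogonal to `t` up to
#'   rounding.
#' @export
perpendicular_gradient <- function(g, t) {
  if (length(g) != length(t)) stop("gradient and tangent lengths differ")
  nt <- sqrt(sum(t^2))
  if (abs(nt - 1) > 1e-8) stop("tangent must have unit norm")
  g - sum(t * g) * t
}

# interpolator closure for a config (icsys reused across all segments)
make_interpolator <- function(config, icsys = NULL) {
  if (config$interpolator == "ric") {
    if (is.null(icsys)) stop("RIC interpolation requires an IC system")
    function(left, right)
      ric_interpolate(left, right, icsys, nfractions = config$dense_fractions)
  } else {
    function(left, right)
      lst_interpolate(left, right, nfractions = config$dense_fractions,
                      w = config$lst_w)
  }
}

#' Interpolation step size from the initial endpoint pair
#'
#' `s` is the arc length of a dense interpolated path connecting reactant
#' and product (using the configured interpolator) divided by `n_nodes`.
#'
#' @param reactant,product aligned endpoint geometries.
#' @param config an [fsm_config()].
#' @param icsys IC system (required for the RIC interpolator; built
#'   automatically when omitted).
#' @return step size in Angstrom.
#' @export
compute_step_size <- function(reactant, product, config = fsm_config(),
                              icsys = NULL) {
  check_same_composition(reactant, product)
  if (config$interpolator == "ric" && is.null(icsys))
    icsys <- build_ic_system(reactant, product, config$bond_scale)
  interp <- make_interpolator(config, icsys)(reactant, product)
  total <- max(interp$path$arc)
  if (total <= 0) stop("identical endpoints: zero-length path")
  total / config$n_nodes
}

# L-BFGS two-loop recursion over stored correction pairs
lbfgs_direction <- function(g, mem) {
  q <- g
  m <- length(mem$s)
  if (m == 0L) return(-g)
  alpha <- numeric(m)
  for (i in m:1) {
    alpha[i] <- mem$rho[[i]] * sum(mem$s[[i]] * q)
    q <- q - alpha[i] * mem$y[[i]]
  }
  gamma <- sum(mem$s[[m]] * mem$y[[m]]) / sum(mem$y[[m]]^2)
  r <- gamma * q
  for (i in 1:m) {
    beta <- mem$rho[[i]] * sum(mem$y[[i]] * r)
    r <- r + (alpha[i] - beta) * mem$s[[i]]
  }
  -r
}

#' Optimize one frontier node perpendicular to the pathway
#'
#' Minimizes the energy with the gradient replaced by its component
#' perpendicular to the (fixed) tangent, using a bounded limited-memory
#' quasi-Newton scheme (10 correction pairs) in Cartesian coordinates. No
#' coordinate moves more than `max_disp` during a single optimization
#' step (bound applied relative to each step's start), and each step's
#' length is set by a backtracking Armijo line search (`c1 = 1e-4`, step
#' halving) using at most `n_ls` energy/gradient evaluations; on
#' exhaustion the best-seen point is accepted. Optimization stops early
#' when the perpendicular-gradient max-norm drops below `grad_tol`.
#'
#' @param node starting [geometry()].
#' @param tangent unit tangent (length 3N).
#' @param calculator an `fsm_calculator`.
#' @param config an [fsm_config()].
#' @param eval0 optional precomputed `evaluate()` result at `node` (counts
#'   toward the evaluation budget of the caller, not this node).
#' @return list with `geometry`, `energy`, `gradient`, `evals` (total
#'   energy/gradient calls used, `<= n_opt * (1 + n_ls)`), and
#'   `step_history` (matrix of accepted per-step displacements).
#' @export
optimize_node <- function(node, tangent, calculator, config = fsm_config(),
                          eval0 = NULL) {
  nt <- sqrt(sum(tangent^2))
  if (abs(nt - 1) > 1e-8) stop("tangent must have unit norm")
  evals <- 0L
  ev <- function(geom) {
    evals <<- evals + 1L
    evaluate(calculator, geom)
  }
  cur <- if (is.null(eval0)) ev(node) else eval0
  if (!is.finite(cur$energy))
    stop("non-finite energy at node starting geometry")
  x <- coords_vector(node)
  gperp <- perpendicular_gradient(cur$gradient, tangent)
  mem <- list(s = list(), y = list(), rho = list())
  history <- list()
  failed <- FALSE
  nsteps <- 0L
  while (nsteps < config$n_opt && max(abs(gperp)) >= config$grad_tol) {
    nsteps <- nsteps + 1L
    d <- lbfgs_direction(gperp, mem)
    d <- d - sum(tangent * d) * tangent       # keep motion orthogonal
    if (sum(d * gperp) >= 0) d <- -gperp      # enforce descent direction
    if (max(abs(d)) == 0) break
    alpha0 <- min(1, config$max_disp / max(abs(d)))
    alpha <- alpha0
    slope <- sum(gperp * d)
    best <- NULL
    accepted <- NULL
    for (ls in seq_len(config$n_ls)) {
      trial_x <- x + alpha * d
      trial <- tryCatch(ev(with_coords(node, trial_x)),
                        error = function(e) NULL)
      if (is.null(trial) || !is.finite(trial$energy)) { failed <- TRUE; break }
      if (is.null(best) || trial$energy < best$res$energy)
        best <- list(x = trial_x, res = trial)
      if (trial$energy <= cur$energy + 1e-4 * alpha * slope) {
        accepted <- list(x = trial_x, res = trial)
        break
      }
      alpha <- alpha / 2
    }
    if (failed) break
    if (is.null(accepted)) {
      # line search exhausted: accept the best-seen point if it improves
      if (!is.null(best) && best$res$energy < cur$energy) accepted <- best
      else break
    }
    gperp_new <- perpendicular_gradient(accepted$res$gradient, tangent)
    sv <- accepted$x - x
    yv <- gperp_new - gperp
    if (sum(sv * yv) > 1e-12) {
      mem$s <- c(mem$s, list(sv)); mem$y <- c(mem$y, list(yv))
      mem$rho <- c(mem$rho, list(1 / sum(sv * yv)))
      if (length(mem$s) > 10L) {
        mem$s <- mem$s[-1L]; mem$y <- mem$y[-1L]; mem$rho <- mem$rho[-1L]
      }
    }
    history[[length(history) + 1L]] <- sv
    x <- accepted$x
    cur <- accepted$res
    gperp <- gperp_new
  }
  list(geometry = with_coords(node, x), energy = cur$energy,
       gradient = cur$gradient, evals = evals,
       step_history = if (length(history))
         do.call(rbind, history) else matrix(0, 0L, length(x)),
       failed = failed)
}

#' Run the freezing string method
#'
#' Grows two strings inward from the reactant and the product. Each
#' growth cycle interpolates a dense path between the current frontier
#' nodes, places new frontier nodes at arc distance `s` from each end,
#' assigns tangents from a cubic spline through the interpolated pathway,
#' optimizes each new node perpendicular to its tangent, and freezes it.
#' When the frontier gap drops below `join_threshold * s` the strings are
#' joined (a single midpoint node is placed first when the gap is between
#' that and `2 s`). The highest-energy node of the joined string is the
#' transition-state guess.
#'
#' @param reactant,product endpoint geometries (same symbols/ordering).
#' @param calculator an `fsm_calculator`.
#' @param config an [fsm_config()].
#' @return an `fsm_string` object: `path` (reactant-to-product
#'   [fsm_path()]), `energies`, `ts_guess` geometry and `ts_index`,
#'   `s`, `status` (`"joined"` or `"failed"`), `grad_calls`,
#'   `node_evals`, `step_history`, `config`, `icsys` (RIC runs), and a
#'   per-cycle `log`.
#' @export
run_fsm <- function(reactant, product, calculator, config = fsm_config()) {
  check_same_composition(reactant, product)
  log <- character(0L)
  note <- function(...) log <<- c(log, sprintf(...))
  count0 <- eval_count(calculator)

  if (config$align && reactant$natoms >= 2L) {
    al <- kabsch_align(reactant, product)
    product <- al$geometry
    note("aligned product onto reactant (rmsd %.6f A)", al$rmsd)
  }

  evR <- evaluate(calculator, reactant)
  evP <- evaluate(calculator, product)
  if (!is.finite(evR$energy) || !is.finite(evP$energy)) {
    note("non-finite endpoint energy: run failed")
    return(structure(list(status = "failed", log = log,
                          grad_calls = eval_count(calculator) - count0),
                     class = "fsm_string"))
  }

  icsys <- NULL
  if (config$interpolator == "ric") {
    if (reactant$natoms < 2L)
      stop("RIC interpolation requires at least 2 atoms; use the LST interpolator")
    icsys <- build_ic_system(reactant, product, config$bond_scale)
    note("IC system: %d primitives, %d delocalized coordinates",
         length(icsys$primitives), ncol(icsys$U))
  }
  interp_fn <- make_interpolator(config, icsys)
  s <- compute_step_size(reactant, product, config, icsys)
  note("step size s = %.6f A (n_nodes = %d)", s, config$n_nodes)

  left <- list(reactant); right <- list(product)
  e_left <- evR$energy; e_right <- evP$energy
  node_evals <- c(left = 1L, right = 1L)
  step_history <- list()
  status <- "growing"
  cycle <- 0L

  place_and_optimize <- function(interp, arc_pos, side) {
    new_node <- take_step(interp, from_left = (side == "left"),
                          s = if (side == "left") arc_pos else arc_pos)
    tan_arc <- if (side == "left") arc_pos else max(interp$path$arc) - arc_pos
    tangent <- tangent_at_arc(interp$path, tan_arc)
    res <- optimize_node(new_node, tangent, calculator, config)
    res
  }

  while (status == "growing") {
    cycle <- cycle + 1L
    if (cycle > 4L * config$n_nodes) { status <- "failed"; note("growth stalled"); break }
    interp <- tryCatch(interp_fn(left[[length(left)]], right[[length(right)]]),
                       error = function(e) e)
    if (inherits(interp, "error")) {
      status <- "failed"
      note("interpolation failed at cycle %d: %s", cycle, conditionMessage(interp))
      break
    }
    gap <- max(interp$path$arc)
    note("cycle %d: frontier gap %.6f A (s = %.6f)", cycle, gap, s)
    if (gap <= config$join_threshold * s) { status <- "joined"; break }
    single <- gap < 2 * s
    sides <- if (single) "left" else c("left", "right")
    place_s <- if (single) gap / 2 else s
    ok <- TRUE
    for (side in sides) {
      res <- tryCatch(place_and_optimize(interp, place_s, side),
                      error = function(e) e)
      if (inherits(res, "error") || isTRUE(res$failed)) {
        status <- "failed"
        note("node optimization failed at cycle %d (%s side)", cycle, side)
        ok <- FALSE
        break
      }
      note("cycle %d: froze %s node, E = %.8g, %d evaluations",
           cycle, side, res$energy, res$evals)
      if (side == "left") {
        left[[length(left) + 1L]] <- res$geometry
        e_left <- c(e_left, res$energy)
      } else {
        right[[length(right) + 1L]] <- res$geometry
        e_right <- c(e_right, res$energy)
      }
      node_evals <- c(node_evals, res$evals)
      step_history[[length(step_history) + 1L]] <- res$step_history
    }
    if (!ok) break
    if (single && status == "growing") {
      # after the lone midpoint node the strings have met
      status <- "joined"
      note("cycle %d: midpoint node placed, strings joined", cycle)
    }
  }

  grad_calls <- eval_count(calculator) - count0
  if (status != "joined") {
    return(structure(list(status = "failed", log = log, s = s,
                          left = left, right = right,
                          grad_calls = grad_calls, config = config),
                     class = "fsm_string"))
  }
  nodes <- c(left, rev(right))
  energies <- c(e_left, rev(e_right))
  ts_index <- which.max(energies)
  note("joined: %d nodes, TS guess at node %d (E = %.8g), %d gradient calls",
       length(nodes), ts_index, energies[ts_index], grad_calls)
  structure(list(
    path = fsm_path(nodes), energies = energies,
    ts_guess = nodes[[ts_index]], ts_index = ts_index,
    s = s, status = status, grad_calls = grad_calls,
    node_evals = node_evals, step_history = step_history,
    icsys = icsys, config = config, log = log
  ), class = "fsm_string")
}

#' @export
print.fsm_string <- function(x, ...) {
  if (x$status != "joined") {
    cat(sprintf("<fsm_string: status %s, %d gradient calls>\n",
                x$status, x$grad_calls))
    return(invisible(x))
  }
  cat(sprintf(
    "<fsm_string: %d nodes, TS guess at node %d, E_max = %.6g, %d gradient calls>\n",
    length(x$path$nodes), x$ts_index, max(x$energies), x$grad_calls))
  invisible(x)
}

#' Write the standard FSM output bundle
#'
#' Writes `string.xyz` (multi-frame, reactant to product, energies in the
#' comment lines), `profile.tsv` (node index, arc length, energy),
#' `ts_guess.xyz`, `run.log`, and `config.yaml` into a directory.
#'
#' @param state a joined `fsm_string` from [run_fsm()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fsm_output <- function(state, dir) {
  if (state$status != "joined") stop("cannot write output for a failed run")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_xyz(state$path, file.path(dir, "string.xyz"),
            energies = state$energies)
  prof <- data.frame(node = seq_along(state$energies),
                     arc = state$path$arc, energy = state$energies)
  utils::write.table(prof, file.path(dir, "profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_xyz(state$ts_guess, file.path(dir, "ts_guess.xyz"),
            energies = state$energies[state$ts_index])
  writeLines(state$log, file.path(dir, "run.log"))
  cfg <- state$config
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1L))],
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
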