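# Pluggable energy/gradient backends. Every calculator is a closure
# object with a shared evaluation counter; evaluate() is the single
# contract the string machinery uses.

new_calculator <- function(fn, label, natoms = NULL) {
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  structure(list(fn = fn, label = label, natoms = natoms, env = env),
            class = "fsm_calculator")
}

#' @export
print.fsm_calculator <- function(x, ...) {
  cat(sprintf("<fsm_calculator: %s, %d evaluations>\n", x$label, eval_count(x)))
  invisible(x)
}

#' Evaluate energy and gradient of a geometry
#'
#' The single contract all backends implement: returns the energy and the
#' analytic Cartesian gradient at `geom`, incrementing the calculator's
#' evaluation counter exactly once per call.
#'
#' @param calculator an `fsm_calculator` (see [mb_calculator()],
#'   [toyff_calculator()], [external_calculator()]).
#' @param geom a [geometry()].
#' @return list with `energy` (scalar), `gradient` (length-3N numeric,
#'   energy units per Angstrom), and `eval_index` (the running counter).
#' @export
evaluate <- function(calculator, geom) UseMethod("evaluate")

#' @export
evaluate.fsm_calculator <- function(calculator, geom) {
  if (!is.null(calculator$natoms) && geom$natoms != calculator$natoms)
    stop(calculator$label, " expects ", calculator$natoms, " atom(s)")
  res <- calculator$fn(geom)
  if (length(res$gradient) != 3L * geom$natoms)
    stop("calculator returned a gradient of wrong length")
  calculator$env$count <- calculator$env$count + 1L
  list(energy = res$energy, gradient = res$gradient,
       eval_index = calculator$env$count)
}

#' Evaluation counter of a calculator
#'
#' @param calculator an `fsm_calculator`.
#' @return integer count of [evaluate()] calls since creation/reset.
#' @export
eval_count <- function(calculator) calculator$env$count

#' Reset a calculator's evaluation counter
#' @param calculator an `fsm_calculator`.
#' @return the calculator, invisibly.
#' @export
reset_eval_count <- function(calculator) {
  calculator$env$count <- 0L
  invisible(calculator)
}

# Mueller-Brown parameters (standard literature values)
.mb_par <- list(
  A  = c(-200, -100, -170, 15),
  a  = c(-1, -1, -6.5, 0.7),
  b  = c(0, 0, 11, 0.6),
  cc = c(-10, -10, -6.5, 0.7),
  x0 = c(1, 0, -0.5, -1),
  y0 = c(0, 0.5, 1.5, 1)
)

# energy/gradient of the 2-D Mueller-Brown surface at (x, y)
mb_energy_gradient <- function(x, y) {
  p <- .mb_par
  dx <- x - p$x0; dy <- y - p$y0
  ex <- p$A * exp(p$a * dx^2 + p$b * dx * dy + p$cc * dy^2)
  e <- sum(ex)
  gx <- sum(ex * (2 * p$a * dx + p$b * dy))
  gy <- sum(ex * (p$b * dx + 2 * p$cc * dy))
  list(energy = e, gradient = c(gx, gy))
}

#' Mueller-Brown analytic surface calculator
#'
#' The classic 2-D four-Gaussian benchmark surface, represented as a
#' single-atom "molecule" whose x and y coordinates are the surface
#' coordinates; the z coordinate is frozen (zero gradient). Energies are
#' in the surface's own arbitrary units.
#'
#' @return an `fsm_calculator` for 1-atom geometries.
#' @examples
#' calc <- mb_calculator()
#' g <- mb_minimum("A")
#' evaluate(calc, g)$energy
#' @export
mb_calculator <- function() {
  new_calculator(function(geom) {
    eg <- mb_energy_gradient(geom$coords[1L, 1L], geom$coords[1L, 2L])
    list(energy = eg$energy, gradient = c(eg$gradient, 0))
  }, label = "mueller-brown", natoms = 1L)
}

#' Well-known stationary-point starting guesses on the Mueller-Brown surface
#'
#' Returns a 1-atom geometry at the approximate location of a named
#' minimum. `"A"` is the global minimum, `"B"` the minimum across both
#' saddles, `"C"` the intermediate minimum. These are starting guesses;
#' refine with a local optimizer where exact stationary points are needed.
#'
#' @param which one of `"A"`, `"B"`, `"C"`.
#' @return a 1-atom [geometry()] (element tag `"X"` is not used by the
#'   calculator; a hydrogen placeholder is stored).
#' @export
mb_minimum <- function(which = c("A", "B", "C")) {
  which <- match.arg(which)
  xy <- switch(which,
    A = c(-0.558, 1.442),
    B = c(0.623, 0.028),
    C = c(-0.050, 0.467))
  geometry("H", c(xy, 0))
}

#' Toy force-field specification
#'
#' A minimal molecular mechanics form used to exercise the full
#' internal-coordinate stack: Morse bonds
#' `D (1 - exp(-a (r - r0)))^2`, harmonic angles `k/2 (theta - theta0)^2`,
#' cosine torsions `V/2 (1 + cos(n phi - gamma))`, and a soft `(sigma/r)^12`
#' repulsion between atom pairs not covered by a bond term.
#'
#' @param bonds data frame with columns `i, j, D, a, r0`.
#' @param angles data frame with columns `i, j, k, kf, theta0` (theta0 in
#'   radians), or `NULL`.
#' @param torsions data frame with columns `i, j, k, l, V, n, gamma`
#'   (gamma in radians), or `NULL`.
#' @param repulsion list with `eps` and `sigma` for the nonbonded term,
#'   or `NULL` to disable.
#' @return object of class `fsm_toyff_spec`.
#' @export
toyff_spec <- function(bonds, angles = NULL, torsions = NULL,
                       repulsion = list(eps = 0.05, sigma = 2.0)) {
  stopifnot(is.data.frame(bonds), all(c("i", "j", "D", "a", "r0") %in% names(bonds)))
  if (any(bonds$D < 0)) stop("Morse well depths D must be >= 0")
  if (!is.null(angles)) {
    stopifnot(all(c("i", "j", "k", "kf", "theta0") %in% names(angles)))
    if (any(angles$kf < 0)) stop("angle force constants must be >= 0")
  }
  if (!is.null(torsions)) {
    stopifnot(all(c("i", "j", "k", "l", "V", "n", "gamma") %in% names(torsions)))
    if (any(torsions$V < 0)) stop("torsion barriers V must be >= 0")
  }
  structure(list(bonds = bonds, angles = angles, torsions = torsions,
                 repulsion = repulsion),
            class = "fsm_toyff_spec")
}

#' Toy force-field calculator
#'
#' Builds an `fsm_calculator` from a [toyff_spec()]. Gradients are exact:
#' each term's derivative is assembled from the analytic primitive
#' B-matrix rows (chain rule through bond lengths, angles and torsions),
#' so the energy is invariant under rigid rotation and translation.
#'
#' @param spec a [toyff_spec()] or the path of a YAML file written by
#'   [write_toyff()].
#' @return an `fsm_calculator`.
#' @export
toyff_calculator <- function(spec) {
  if (is.character(spec)) spec <- read_toyff(spec)
  stopifnot(inherits(spec, "fsm_toyff_spec"))
  bonded_pairs <- unique(t(apply(spec$bonds[, c("i", "j")], 1L, sort)))
  fn <- function(geom) {
    n3 <- geom$natoms * 3L
    e <- 0; grad <- numeric(n3)
    for (r in seq_len(nrow(spec$bonds))) {
      b <- spec$bonds[r, ]
      pr <- primitive("bond", c(b$i, b$j))
      q <- measure_one(geom, pr)
      ex <- exp(-b$a * (q - b$r0))
      e <- e + b$D * (1 - ex)^2
      dEdq <- 2 * b$D * (1 - ex) * b$a * ex
      grad <- grad + dEdq * b_row_one(geom, pr)
    }
    if (!is.null(spec$angles)) for (r in seq_len(nrow(spec$angles))) {
      a <- spec$angles[r, ]
      pr <- primitive("angle", c(a$i, a$j, a$k))
      q <- measure_one(geom, pr)
      e <- e + a$kf / 2 * (q - a$theta0)^2
      grad <- grad + a$kf * (q - a$theta0) * b_row_one(geom, pr)
    }
    if (!is.null(spec$torsions)) for (r in seq_len(nrow(spec$torsions))) {
      tr <- spec$torsions[r, ]
      pr <- primitive("torsion", c(tr$i, tr$j, tr$k, tr$l))
      q <- measure_one(geom, pr)
      e <- e + tr$V / 2 * (1 + cos(tr$n * q - tr$gamma))
      grad <- grad - tr$V / 2 * tr$n * sin(tr$n * q - tr$gamma) * b_row_one(geom, pr)
    }
    if (!is.null(spec$repulsion) && geom$natoms >= 2L) {
      eps <- spec$repulsion$eps; sig <- spec$repulsion$sigma
      for (i in 1:(geom$natoms - 1L)) for (j in (i + 1L):geom$natoms) {
        if (any(bonded_pairs[, 1L] == i & bonded_pairs[, 2L] == j)) next
        pr <- primitive("distance", c(i, j))
        q <- measure_one(geom, pr)
        e <- e + eps * (sig / q)^12
        grad <- grad - 12 * eps * sig^12 / q^13 * b_row_one(geom, pr)
      }
    }
    list(energy = e, gradient = grad)
  }
  new_calculator(fn, label = "toy-ff")
}

#' Write / read a toy force-field parameter file (YAML)
#'
#' @param spec a [toyff_spec()].
#' @param file path of the YAML parameter file.
#' @return `write_toyff`: the path, invisibly. `read_toyff`: a
#'   [toyff_spec()].
#' @export
write_toyff <- function(spec, file) {
  stopifnot(inherits(spec, "fsm_toyff_spec"))
  obj <- list(
    bonds = lapply(seq_len(nrow(spec$bonds)), function(r) as.list(spec$bonds[r, ])),
    angles = if (is.null(spec$angles)) NULL else
      lapply(seq_len(nrow(spec$angles)), function(r) as.list(spec$angles[r, ])),
    torsions = if (is.null(spec$torsions)) NULL else
      lapply(seq_len(nrow(spec$torsions)), function(r) as.list(spec$torsions[r, ])),
    repulsion = spec$repulsion
  )
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' @rdname write_toyff
#' @export
read_toyff <- function(file) {
  obj <- yaml::read_yaml(file)
  tdf <- function(x) if (is.null(x)) NULL else
    do.call(rbind, lapply(x, function(r) as.data.frame(r)))
  toyff_spec(bonds = tdf(obj$bonds), angles = tdf(obj$angles),
             torsions = tdf(obj$torsions), repulsion = obj$repulsion)
}

#' File-based adapter around an external energy/gradient program
#'
#' Implements file-based data exchange with an external electronic
#' structure (or mock) program. For each evaluation the geometry is
#' written as an XYZ file, the command template is invoked with `{input}`
#' and `{output}` placeholders substituted, and the contract output file
#' is parsed:
#'
#' * optional first header line `# gradient_units: bohr` (gradients are
#'   then converted from Hartree/bohr to Hartree/Angstrom using
#'   1 bohr = 0.52917721092 Angstrom);
#' * first data line: total energy in Hartree;
#' * next N lines: gradient components (3 per line) in Hartree/Angstrom
#'   (or Hartree/bohr with the header above).
#'
#' @param cmd_template shell command containing `{input}` and `{output}`
#'   placeholders.
#' @param workdir directory for exchange files (created if missing).
#' @return an `fsm_calculator` whose energies are Hartree and gradients
#'   Hartree per Angstrom.
#' @export
external_calculator <- function(cmd_template, workdir = tempfile("fsm_ext")) {
  if (!grepl("{input}", cmd_template, fixed = TRUE) ||
      !grepl("{output}", cmd_template, fixed = TRUE))
    stop("cmd_template must contain {input} and {output} placeholders")
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  bohr <- 0.52917721092
  fn <- function(geom) {
    inp <- file.path(workdir, "geom.xyz")
    out <- file.path(workdir, "grad.out")
    errf <- file.path(workdir, "stderr.log")
    if (file.exists(out)) unlink(out)
    write_xyz(geom, inp)
    cmd <- gsub("{input}", shQuote(inp), cmd_template, fixed = TRUE)
    cmd <- gsub("{output}", shQuote(out), cmd, fixed = TRUE)
    status <- system2("sh", c("-c", shQuote(cmd)), stdout = errf, stderr = errf)
    if (status != 0L || !file.exists(out))
      stop("external calculator failed (exit ", status, "); stderr at ", errf)
    lines <- trimws(readLines(out))
    lines <- lines[nzchar(lines)]
    in_bohr <- grepl("gradient_units:\\s*bohr", lines[1L])
    if (startsWith(lines[1L], "#")) lines <- lines[-1L]
    if (length(lines) < 1L + geom$natoms)
      stop("corrupt external output: expected ", 1L + geom$natoms,
           " lines; stderr at ", errf)
    energy <- suppressWarnings(as.numeric(lines[1L]))
    grad <- suppressWarnings(as.numeric(unlist(
      strsplit(lines[2:(1L + geom$natoms)], "[[:space:]]+"))))
    if (is.na(energy) || length(grad) != 3L * geom$natoms || anyNA(grad))
      stop("unparseable external output; stderr at ", errf)
    if (in_bohr) grad <- grad / bohr
    list(energy = energy, gradient = grad)
  }
  new_calculator(fn, label = paste0("external: ", cmd_template))
}
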