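double_well_calculator <- function() {
  # E = (x^2 - 1)^2 + 10 y^2 on a 1-atom system; barrier top at x = 0
  fsmpath:::new_calculator(function(geom) {
    x <- geom$coords[1L, 1L]; y <- geom$coords[1L, 2L]
    list(energy = (x^2 - 1)^2 + 10 * y^2,
         gradient = c(4 * x * (x^2 - 1), 20 * y, 0))
  }, label = "double-well", natoms = 1L)
}

test_that("perpendicular_gradient projects exactly", {
  t <- c(1, 0, 0, 0, 0, 0)
  g <- c(3, 0, 0, 0, 0, 0)
  expect_equal(perpendicular_gradient(g, t), rep(0, 6))
  g2 <- c(0, 2, -1, 0, 0, 0.5)
  expect_equal(perpendicular_gradient(g2, t), g2)

  set.seed(3)
  for (k in 1:10) {
    t <- rnorm(9); t <- t / sqrt(sum(t^2))
    g <- rnorm(9)
    gp <- perpendicular_gradient(g, t)
    expect_lt(abs(sum(t * gp)), 1e-12)
    expect_equal(sum(g^2), sum(gp^2) + sum(t * g)^2, tolerance = 1e-10)
  }
  expect_error(perpendicular_gradient(g, 2 * t), "unit norm")
})

test_that("compute_step_size divides the interpolated arc length by n_nodes", {
  d1 <- build_fixture(fixture_spec("diatomic", r = 1.0))
  d9 <- geom_with(d1, coords_vec(d1) + c(0, 0, 0, 9, 0, 0))
  cfg <- fsm_config(n_nodes = 9, interpolator = "lst")
  expect_equal(compute_step_size(d1, d9, cfg), 1.0, tolerance = 1e-6)

  expect_error(compute_step_size(d1, d1, cfg), "zero-length")

  bb <- butane_reaction()
  ics <- build_ic_system(bb$reactant, bb$product)
  s18 <- compute_step_size(bb$reactant, bb$product,
                           fsm_config(n_nodes = 18), ics)
  s9 <- compute_step_size(bb$reactant, bb$product,
                          fsm_config(n_nodes = 9), ics)
  expect_equal(s9, 2 * s18, tolerance = 1e-12)
})

test_that("optimize_node respects the projector, the bounds, and the budget", {
  # already converged: unchanged geometry, exactly one evaluation
  calc <- double_well_calculator()
  g <- geometry("H", c(0, 0, 0))  # x = 0: g = 0
  t <- c(1, 0, 0)
  res <- optimize_node(g, t, calc, fsm_config(n_nodes = 6, interpolator = "lst"))
  expect_equal(res$geometry$coords, g$coords)
  expect_equal(res$evals, 1L)

  # isotropic bowl with tangent along x: motion is confined orthogonally
  bowl <- fsmpath:::new_calculator(function(geom) {
    x <- coords_vec(geom)
    list(energy = sum(x^2), gradient = 2 * x)
  }, label = "bowl")
  start <- geometry("H", c(0.2, 0.25, -0.1))
  res <- optimize_node(start, t, bowl,
                       fsm_config(n_nodes = 6, n_opt = 4, interpolator = "lst"))
  disp <- coords_vec(res$geometry) - coords_vec(start)
  expect_lt(abs(sum(disp * t)), 1e-8)
  expect_lt(abs(coords_vec(res$geometry)[2L]), 0.25)  # moved downhill in y

  # steep quartic: every accepted step obeys the 0.3 A per-coordinate cap
  steep <- fsmpath:::new_calculator(function(geom) {
    x <- coords_vec(geom)
    list(energy = 100 * sum((x - 3)^4), gradient = 400 * (x - 3)^3)
  }, label = "steep")
  cfg <- fsm_config(n_nodes = 6, n_opt = 5, n_ls = 3, interpolator = "lst")
  res <- optimize_node(geometry("H", c(0, 0, 0)), c(0, 0, 1), steep, cfg)
  expect_gt(nrow(res$step_history), 0L)
  expect_lte(max(abs(res$step_history)), 0.3 + 1e-12)
  expect_lte(res$evals, cfg$n_opt * (1L + cfg$n_ls))
})

test_that("run_fsm localizes the double-well barrier and keeps the string symmetric", {
  calc <- double_well_calculator()
  a <- geometry("H", c(-1, 0, 0))
  b <- geometry("H", c(1, 0, 0))
  cfg <- fsm_config(n_nodes = 8, n_opt = 2, n_ls = 3, interpolator = "lst")
  st <- run_fsm(a, b, calc, cfg)
  expect_equal(st$status, "joined")
  xs <- vapply(st$path$nodes, function(g) g$coords[1L, 1L], numeric(1L))
  expect_equal(xs, -rev(xs), tolerance = 1e-8)   # left-right exchange symmetry
  expect_lt(abs(st$ts_guess$coords[1L, 1L]), 0.2) # barrier top at x = 0
  expect_equal(st$energies[st$ts_index], max(st$energies))
})

test_that("run_fsm bookkeeping: counters, node counts, determinism", {
  bb <- butane_reaction()
  calc <- toyff_calculator(bb$spec)
  cfg <- fsm_config(n_nodes = 10, n_opt = 2, n_ls = 3, interpolator = "ric")

  reset_eval_count(calc)
  st <- run_fsm(bb$reactant, bb$product, calc, cfg)
  expect_equal(st$status, "joined")
  expect_equal(st$grad_calls, eval_count(calc))
  expect_equal(st$grad_calls, sum(st$node_evals))
  nn <- length(st$path$nodes)
  expect_gte(nn, cfg$n_nodes - 2L)
  expect_lte(nn, cfg$n_nodes + 2L)
  # per-node budget: endpoints use 1 evaluation, interior nodes at most
  # 1 + n_opt * n_ls
  expect_true(all(st$node_evals <= 1L + cfg$n_opt * cfg$n_ls))
  # per-step displacement bound across the whole run
  for (h in st$step_history)
    if (nrow(h)) expect_lte(max(abs(h)), cfg$max_disp + 1e-12)

  # bit-identical rerun
  st2 <- run_fsm(bb$reactant, bb$product, toyff_calculator(bb$spec), cfg)
  expect_identical(lapply(st$path$nodes, `[[`, "coords"),
                   lapply(st2$path$nodes, `[[`, "coords"))
  expect_identical(st$energies, st2$energies)
  expect_identical(st$grad_calls, st2$grad_calls)
})

test_that("n_opt = 0 reduces run_fsm to pure interpolation plus energy evaluation", {
  bb <- butane_reaction()
  cfg <- fsm_config(n_nodes = 8, n_opt = 0, n_ls = 3, interpolator = "ric")
  calc <- toyff_calculator(bb$spec)
  st <- run_fsm(bb$reactant, bb$product, calc, cfg)
  expect_equal(st$status, "joined")
  # every node used exactly one evaluation (energy for TS-guess selection)
  expect_true(all(st$node_evals == 1L))

  # independent reconstruction of the same growth loop from the public
  # interpolation API, without any optimizer involvement
  al <- kabsch_align(bb$reactant, bb$product)
  ics <- build_ic_system(bb$reactant, al$geometry)
  s <- compute_step_size(bb$reactant, al$geometry, cfg, ics)
  left <- list(bb$reactant); right <- list(al$geometry)
  repeat {
    ri <- ric_interpolate(left[[length(left)]], right[[length(right)]],
                          ics, nfractions = cfg$dense_fractions)
    gap <- max(ri$path$arc)
    if (gap <= cfg$join_threshold * s) break
    if (gap < 2 * s) {
      left[[length(left) + 1L]] <- take_step(ri, TRUE, gap / 2)
      break
    }
    left[[length(left) + 1L]] <- take_step(ri, TRUE, s)
    right[[length(right) + 1L]] <- take_step(ri, FALSE, s)
  }
  manual <- c(left, rev(right))
  expect_equal(length(manual), length(st$path$nodes))
  expect_identical(lapply(st$path$nodes, `[[`, "coords"),
                   lapply(manual, `[[`, "coords"))
})

test_that("the output bundle is written completely", {
  calc <- double_well_calculator()
  st <- run_fsm(geometry("H", c(-1, 0, 0)), geometry("H", c(1, 0, 0)),
                calc, fsm_config(n_nodes = 6, interpolator = "lst"))
  dir <- tempfile("fsmout")
  write_fsm_output(st, dir)
  expect_true(all(file.exists(file.path(
    dir, c("string.xyz", "profile.tsv", "ts_guess.xyz", "run.log",
           "config.yaml")))))
  frames <- read_xyz(file.path(dir, "string.xyz"), multi = TRUE)
  expect_length(frames, length(st$path$nodes))
  expect_equal(attr(frames[[st$ts_index]], "energy"),
               st$energies[st$ts_index], tolerance = 1e-10)
  prof <- read.delim(file.path(dir, "profile.tsv"))
  expect_equal(nrow(prof), length(st$energies))
})

test_that("RIC mode refuses single-atom systems with a clear error", {
  a <- geometry("H", c(-1, 0, 0))
  b <- geometry("H", c(1, 0, 0))
  expect_error(run_fsm(a, b, double_well_calculator(),
                       fsm_config(interpolator = "ric")),
               "at least 2 atoms")
})
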