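test_that("star generator reproduces the printed extrema and enclosed area", {
  s <- make_star(Nb = 160, r_rest = 0.3)
  re <- radius_extrema(s, c(0, 0))
  # extrema of 0.6 + 0.3 sin(8 theta) are hit exactly when Nb is a multiple of 16
  expect_identical(unname(re["r_max"]), 0.9)
  expect_identical(unname(re["r_min"]), 0.3)
  expect_equal(s$ds, 2 * pi * 0.3 / 160)
  expect_identical(s$cb, 0)
  # shoelace area vs the exact polar integral (1/2) int rho^2 dtheta = 0.405 pi;
  # the inscribed 160-gon cuts the lobed corners, so the deficit is ~0.6%
  # and shrinks quadratically with refinement
  expect_equal(enclosed_area(s), 0.405 * pi, tolerance = 1e-2)
  expect_equal(enclosed_area(make_star(Nb = 1280)), 0.405 * pi, tolerance = 1e-4)
})

test_that("filament arc generator places ends, spacing and clamp per the geometry", {
  s <- make_filament_arc(Nb = 30, r = 0.25)
  expect_equal(s$points[30, ], c(0, 0))            # fixed end at the origin
  expect_equal(s$points[1, ], c(-0.25, 0.25))      # free end
  expect_true(all(s$points[, 2] >= 0))             # folded above the wall
  # equal chords: uniform angles on a circular arc
  ch <- sqrt(rowSums((s$points[-1, ] - s$points[-30, ])^2))
  expect_equal(max(ch), min(ch), tolerance = 1e-12)
  expect_equal(s$ds, (pi * 0.25 / 2) / 29)
  expect_equal(s$clamp$node, 30L)
  expect_equal(s$clamp$tangent, c(-1, 0))
  # unstretched at t = 0: chords shorter than ds, so tension vanishes and
  # only bending forces act initially
  expect_true(all(segment_stretch(s) < 1))
  expect_equal(tension(s), rep(0, 29))
})

test_that("circle generator starts at equilibrium and exerts no force", {
  s <- make_circle(Nb = 100, radius = 0.3, center = c(0, 1))
  r <- sqrt((s$points[, 1] - 0)^2 + (s$points[, 2] - 1)^2)
  expect_equal(r, rep(0.3, 100), tolerance = 1e-14)
  re <- radius_extrema(s, c(0, 1))
  expect_equal(unname(re), c(0.3, 0.3), tolerance = 1e-14)
  expect_equal(total_force(s)$F, matrix(0, 100, 2))
  # polygon area of the inscribed regular 100-gon
  expect_equal(enclosed_area(s), pi * 0.09 * sin(2 * pi / 100) * 100 / (2 * pi),
               tolerance = 1e-12)
  expect_equal(enclosed_area(s), 0.28256, tolerance = 1e-4)
})

test_that("generated loops are counterclockwise and simple; shoelace handles a square", {
  sq <- ib_structure(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                     topology = "closed", ds = 1, cs = 0)
  expect_equal(enclosed_area(sq), 1)
  expect_error(enclosed_area(make_filament_arc()), "closed")
  for (s in list(make_star(), make_circle())) {
    expect_gt(enclosed_area(s), 0)  # counterclockwise
    # simple polygon: winding angle sums to exactly one turn
    d <- diff(rbind(s$points, s$points[1, , drop = FALSE]))
    ang <- atan2(d[, 2], d[, 1])
    turn <- diff(c(ang, ang[1]))
    turn <- (turn + pi) %% (2 * pi) - pi
    expect_equal(sum(turn), 2 * pi, tolerance = 1e-9)
  }
})

test_that("packaged scenarios carry the study parameters", {
  st <- ib_scenario("star_relaxation")
  g <- st$config$grid
  expect_equal(c(g$nx, g$ny), c(64, 64))
  expect_equal(c(g$x0, g$x1, g$y0, g$y1), c(-1, 1, -1, 1))
  expect_equal(st$config$mu, 1)
  s1 <- st$config$structures[[1]]
  expect_equal(nrow(s1$points), 160)
  expect_equal(s1$cs, 100)
  bf <- ib_scenario("bending_filament")
  expect_equal(c(bf$config$grid$y0, bf$config$grid$y1), c(0, 2))
  expect_equal(bf$config$dt, 4e-4)
  f <- bf$config$structures[[1]]
  expect_equal(nrow(f$points), 30)
  expect_equal(f$cs, 2)
  expect_equal(f$cb, 0.001)
  fc <- ib_scenario("filament_circle")
  expect_equal(fc$config$dt, 5e-4)
  expect_length(fc$config$structures, 2)
  c2 <- fc$config$structures[[2]]
  expect_equal(nrow(c2$points), 100)
  expect_equal(c2$cs, 0.01)
  expect_identical(c2$cb, 0)   # pure string: bending left off the membrane
  expect_equal(fc$centers[[2]], c(0, 1))
})

test_that("YAML configs round-trip scenario parameters and reject bad keys", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c(
    "name: custom",
    "mu: 2.5",
    "dt: 0.001",
    "n_steps: 3",
    "grid:",
    "  nx: 32",
    "  ny: 32",
    "  extents: [-1, 1, -1, 1]",
    "structures:",
    "  - kind: star",
    "    Nb: 32",
    "    r_rest: 0.3",
    "    cs: 10"
  ), tmp)
  sc <- load_config(tmp)
  expect_equal(sc$config$mu, 2.5)
  expect_equal(sc$config$grid$nx, 32)
  expect_equal(sc$config$structures[[1]]$cs, 10)
  expect_equal(nrow(sc$config$structures[[1]]$points), 32)
  writeLines(c("scenario: star_relaxation", "bogus_key: 1"), tmp)
  expect_error(load_config(tmp), "bogus_key")
  writeLines(c("scenario: no_such"), tmp)
  expect_error(load_config(tmp), "no_such")
  writeLines(c("mu: 1"), tmp)
  expect_error(load_config(tmp), "grid")
})

test_that("command line interface lists, runs and diagnoses", {
  expect_output(ib_cli("list-scenarios"), "star_relaxation")
  out <- tempfile()
  expect_output(
    code <- ib_cli(c("run", "star_relaxation", "--steps", "2", "--out", out,
                     "--snapshot-every", "1")),
    "Immersed boundary Stokes simulation")
  expect_true(file.exists(file.path(out, "star_relaxation_diagnostics.csv")))
  expect_true(file.exists(file.path(out, "star_relaxation_p_000001.csv")))
  expect_true(file.exists(file.path(out, "star_relaxation_structure1_trajectory.csv")))
  expect_output(ib_cli(c("diagnose", out)), "wrote")
  expect_true(file.exists(file.path(out, "star_relaxation_diagnostics.md")))
  unlink(out, recursive = TRUE)
})
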