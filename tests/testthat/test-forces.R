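circle_struct <- function(R = 0.63, r0 = 0.3, N = 160, cs = 100, cb = 0) {
  th <- 2 * pi * (seq_len(N) - 1) / N
  ib_structure(cbind(R * cos(th), R * sin(th)), topology = "closed",
               ds = 2 * pi * r0 / N, cs = cs, cb = cb)
}

test_that("segment stretch measures chord length over rest spacing", {
  # straight chain at rest spacing
  ds <- 0.1
  chain <- ib_structure(cbind(seq(0, 0.5, by = ds), 0), topology = "open", ds = ds, cs = 1)
  expect_equal(segment_stretch(chain), rep(1, 5), tolerance = 1e-14)
  # circle: chord/arclength ratio
  s <- circle_struct(R = 0.63, r0 = 0.3, N = 160)
  expected <- 2 * 0.63 * sin(pi / 160) / (2 * pi * 0.3 / 160)
  expect_equal(segment_stretch(s), rep(expected, 160), tolerance = 1e-12)
  expect_equal(expected, 2.0999, tolerance = 1e-4)
  # isometry invariance under rigid rotation
  th <- 0.77; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  s2 <- s; s2$points <- s$points %*% t(Rm)
  expect_equal(segment_stretch(s2), segment_stretch(s), tolerance = 1e-12)
})

test_that("tension is one-sided: taut segments pull, slack segments carry zero", {
  s <- circle_struct(R = 0.3, r0 = 0.3, N = 64, cs = 100)  # chords < arc: slack
  expect_true(all(segment_stretch(s) < 1))
  expect_equal(tension(s), rep(0, 64))
  # compressed straight chain
  chain <- ib_structure(cbind(seq(0, 0.4, by = 0.08), 0), topology = "open",
                        ds = 0.1, cs = 5)
  expect_true(all(segment_stretch(chain) < 1))
  expect_equal(tension(chain), rep(0, 5))
  # stretch 2.1 at cs = 100 -> T = 110
  chain2 <- ib_structure(cbind(seq(0, 1.05, by = 0.21), 0), topology = "open",
                         ds = 0.1, cs = 100)
  expect_equal(tension(chain2), rep(110, 5), tolerance = 1e-10)
})

test_that("stretching force is radial on a taut circle and telescopes to zero", {
  s <- circle_struct(R = 0.63, r0 = 0.3, N = 160, cs = 100)
  Fs <- stretching_force(s)
  # zero net force (closed chain telescoping)
  expect_lt(max(abs(colSums(Fs))), 1e-11 * max(abs(Fs)))
  # radial, inward, uniform magnitude
  rhat <- s$points / sqrt(rowSums(s$points^2))
  rad <- rowSums(Fs * rhat)
  tang <- Fs - rad * rhat
  expect_lt(max(abs(tang)), 1e-9 * max(abs(rad)))
  expect_true(all(rad < 0))
  expect_equal(max(rad), min(rad), tolerance = 1e-9)
  # rest-state and zero-coefficient fixed points
  expect_equal(stretching_force(circle_struct(R = 0.3, r0 = 0.3, N = 64)),
               matrix(0, 64, 2))
  chain <- ib_structure(cbind(seq(0, 0.5, by = 0.1), 0), topology = "open",
                        ds = 0.1, cs = 3)
  expect_equal(stretching_force(chain), matrix(0, 6, 2), tolerance = 1e-12)
})

test_that("forces are translation invariant and rotation equivariant", {
  set.seed(13)
  s <- circle_struct(R = 0.5, r0 = 0.3, N = 40, cs = 7, cb = 0.02)
  s$points <- s$points + 0.02 * matrix(rnorm(80), 40, 2)  # roughen the loop
  F0 <- total_force(s)$F
  sT <- s; sT$points <- sweep(s$points, 2, c(0.31, -0.12), `+`)
  expect_equal(total_force(sT)$F, F0, tolerance = 1e-9)
  th <- 1.13; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sR <- s; sR$points <- s$points %*% t(Rm)
  expect_equal(total_force(sR)$F, F0 %*% t(Rm), tolerance = 1e-9)
  # no self-propulsion: net force on the closed loop vanishes
  expect_lt(max(abs(colSums(F0) * s$ds)), 1e-11 * max(abs(F0)))
})

test_that("closed-loop bending force is radial with zero sum; straight filament is force-free", {
  s <- circle_struct(R = 0.5, r0 = 0.3, N = 64, cs = 0, cb = 0.01)
  Fb <- bending_force(s)
  expect_lt(max(abs(colSums(Fb))), 1e-10 * max(abs(Fb)))
  rhat <- s$points / sqrt(rowSums(s$points^2))
  rad <- rowSums(Fb * rhat)
  tang <- Fb - rad * rhat
  expect_lt(max(abs(tang)), 1e-8 * max(abs(rad)))
  expect_equal(max(rad), min(rad), tolerance = 1e-8)
  # straight filament aligned with its clamp tangent: interior forces vanish
  n <- 12
  # free end at (0.55, 0), clamped at the origin: the last segment runs in
  # the -x direction, matching the clamp tangent datum (-1, 0)
  pts <- cbind(seq(0.55, 0, length.out = n), 0)
  f <- ib_structure(pts, topology = "open", ds = 0.05, cs = 0, cb = 0.001,
                    clamp = list(fixed_position = c(0, 0), tangent = c(-1, 0)))
  Fb2 <- bending_force(f)
  expect_lt(max(abs(Fb2[2:(n - 1), ])), 1e-10)
  expect_error(bending_force(ib_structure(pts, topology = "open", ds = 0.05,
                                          cs = 0, cb = 0.001)), "clamp")
})

test_that("filament forces match an independently coded staggered-scheme oracle", {
  s <- make_filament_arc(Nb = 30, r = 0.25, cs = 2, cb = 0.001)
  ora <- oracle_filament_forces(s$points, s$ds, 2, 0.001)
  expect_equal(stretching_force(s), ora$Fs, tolerance = 1e-12)
  expect_equal(bending_force(s), ora$Fb, tolerance = 1e-12)
  expect_equal(total_force(s)$F, ora$F, tolerance = 1e-12)
  # and again on a randomly perturbed taut configuration
  set.seed(31)
  s2 <- s
  s2$points <- s$points * 1.4 + 0.01 * matrix(rnorm(60), 30, 2)
  s2$points[30, ] <- c(0, 0)
  ora2 <- oracle_filament_forces(s2$points, s2$ds, 2, 0.001)
  expect_equal(total_force(s2)$F, ora2$F, tolerance = 1e-11)
})

test_that("stretching force is the negative gradient of the discrete stretch energy", {
  # E = (cs/2) sum (stretch-1)^2 ds over taut midpoints; directional
  # derivative along a random perturbation must equal -sum F.v ds
  set.seed(8)
  s <- circle_struct(R = 0.6, r0 = 0.3, N = 48, cs = 10)
  energy <- function(P) {
    st <- s; st$points <- P
    str <- segment_stretch(st)
    0.5 * st$cs * sum(pmax(str - 1, 0)^2) * st$ds
  }
  v <- matrix(rnorm(96), 48, 2)
  eps <- 1e-6
  dE <- (energy(s$points + eps * v) - energy(s$points - eps * v)) / (2 * eps)
  Fv <- -sum(stretching_force(s) * v) * s$ds
  expect_equal(dE, Fv, tolerance = 1e-5)
})

test_that("degenerate chains are reported: coincident nodes break the tangent", {
  pts <- cbind(c(0, 0.1, 0.1, 0.2, 0.3), 0)
  s <- ib_structure(pts, topology = "open", ds = 0.05, cs = 2)
  expect_error(stretching_force(s), "zero-length segment at index 2")
  # with cs = 0 no tangent is needed and the force is just zero
  s0 <- ib_structure(pts, topology = "open", ds = 0.05, cs = 0)
  expect_equal(total_force(s0)$F, matrix(0, 5, 2))
})
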