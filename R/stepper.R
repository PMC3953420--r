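#' Simulation configuration
#'
#' Bundles the grid, fluid viscosity, time stepping and the immersed
#' structures into a validated configuration for [ib_run()]. Because the
#' flow is inertialess, the fields are slaved to the instantaneous elastic
#' forces and the only dynamics is the forward-Euler motion of the
#' structures.
#'
#' Exactly how long to run can be given as a step count (\code{n_steps}), an
#' end time (\code{t_end}), or a convergence tolerance on the maximum
#' Lagrangian node speed (\code{tol_speed}, with \code{max_steps} as a
#' safety cap). A time-step schedule may be supplied as a two-column matrix
#' or data frame \code{(t, dt)}: from time \code{t} onward the step \code{dt}
#' applies, which supports starting with a small step while the elastic
#' forces are large and relaxing it later.
#'
#' @param grid a [periodic_grid()].
#' @param structures list of [ib_structure()] objects (at least one).
#' @param mu fluid viscosity (> 0).
#' @param dt time step (> 0).
#' @param n_steps,t_end,tol_speed stopping rules; at least one must be given.
#' @param max_steps safety cap when running to convergence.
#' @param dt_schedule optional data frame or matrix with columns \code{t},
#'   \code{dt}.
#' @param name scenario name used in output files.
#' @return object of class \code{"sim_config"}.
#' @export
sim_config <- function(grid, structures, mu = 1, dt,
                       n_steps = NULL, t_end = NULL, tol_speed = NULL,
                       max_steps = 200000L, dt_schedule = NULL,
                       name = "simulation") {
  if (!inherits(grid, "periodic_grid")) stop("'grid' must be a periodic_grid")
  if (!is.list(structures) || length(structures) == 0L ||
      !all(vapply(structures, inherits, logical(1), "ib_structure")))
    stop("'structures' must be a non-empty list of ib_structure objects")
  if (!is.numeric(mu) || mu <= 0) stop("'mu' must be > 0")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  if (is.null(n_steps) && is.null(t_end) && is.null(tol_speed))
    stop("give at least one stopping rule: n_steps, t_end or tol_speed")
  if (!is.null(dt_schedule)) {
    dt_schedule <- as.data.frame(dt_schedule)
    if (!all(c("t", "dt") %in% names(dt_schedule)))
      stop("'dt_schedule' needs columns t and dt")
    dt_schedule <- dt_schedule[order(dt_schedule$t), ]
    if (any(dt_schedule$dt <= 0)) stop("'dt_schedule': dt must be > 0")
  }
  structure(list(grid = grid, structures = structures, mu = mu, dt = dt,
                 n_steps = n_steps, t_end = t_end, tol_speed = tol_speed,
                 max_steps = as.integer(max_steps), dt_schedule = dt_schedule,
                 name = name),
            class = "sim_config")
}

current_dt <- function(config, time) {
  dt <- config$dt
  sch <- config$dt_schedule
  if (!is.null(sch)) {
    active <- sch$t <= time + 1e-15
    if (any(active)) dt <- sch$dt[max(which(active))]
  }
  dt
}

new_state <- function(config) {
  list(time = 0, structures = config$structures, fields = NULL, step = 0L)
}

#' Solve the instantaneous Stokes fields for a set of structures
#'
#' The elliptic core of the method: Lagrangian elastic forces from all
#' structures are spread into one Eulerian force density \code{(fx, fy)};
#' the pressure solves \code{lap p = div f}; each velocity component then
#' solves \code{mu lap u = dp/dx - fx} (and likewise for v). The pressure
#' solve uses the wide-stencil Laplacian that is the exact composition of
#' the central-difference divergence and gradient, so the velocity field
#' that follows is discretely divergence-free to round-off (see
#' [poisson_solve()]); the velocity solves use the 5-point operator. All
#' solves are exact and gauge-fixed to zero mean; removed right-hand-side
#' means are reported (nonzero on the velocity equations when the
#' structures exert a net force on the box).
#'
#' @param structures list of [ib_structure()] objects.
#' @param grid a [periodic_grid()].
#' @param mu viscosity.
#' @return list with fields \code{u}, \code{v}, \code{p}, \code{fx},
#'   \code{fy}, the per-structure \code{forces}, and \code{removed_means}
#'   for the three Poisson solves.
#' @export
compute_fields <- function(structures, grid, mu = 1) {
  fx <- matrix(0, grid$nx, grid$ny)
  fy <- matrix(0, grid$nx, grid$ny)
  forces <- vector("list", length(structures))
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    lf <- total_force(s)
    if (!all(is.finite(lf$F)))
      stop(sprintf("non-finite Lagrangian force on structure '%s'", s$label))
    forces[[i]] <- lf
    sp <- ib_spread(grid, s$points, lf$F, s$ds)
    fx <- fx + sp$x
    fy <- fy + sp$y
  }
  sol_p <- poisson_solve(grid, divergence(grid, fx, fy), stencil = "wide")
  p <- sol_p$solution
  gp <- central_gradient(grid, p)
  sol_u <- poisson_solve(grid, (gp$x - fx) / mu)
  sol_v <- poisson_solve(grid, (gp$y - fy) / mu)
  list(u = sol_u$solution, v = sol_v$solution, p = p, fx = fx, fy = fy,
       forces = forces,
       removed_means = c(p = sol_p$removed_mean, u = sol_u$removed_mean,
                         v = sol_v$removed_mean))
}

#' Advance the simulation by one forward-Euler step
#'
#' Computes the instantaneous fields with [compute_fields()], interpolates
#' the fluid velocity to every Lagrangian node, and advances each node by
#' \code{dt * U}. Pinned clamp nodes are held at their fixed position. A
#' blow-up guard watches the largest node displacement per step: beyond half
#' a grid cell a warning is logged in the diagnostics; beyond two cells the
#' step aborts, since the explicit scheme has left its stability envelope.
#'
#' @param state list with \code{time}, \code{structures}, \code{step} (as
#'   produced by [ib_run()] internals or a previous \code{ib_step} call).
#' @param config a [sim_config()].
#' @return updated state; \code{state$fields} holds the fields just used,
#'   \code{state$diag} the per-step diagnostics row.
#' @export
ib_step <- function(state, config) {
  grid <- config$grid
  dt <- current_dt(config, state$time)
  fl <- compute_fields(state$structures, grid, config$mu)
  hmin <- min(grid$hx, grid$hy)
  max_speed <- 0
  warned <- FALSE
  for (i in seq_along(state$structures)) {
    s <- state$structures[[i]]
    U <- ib_interpolate(grid, fl$u, fl$v, s$points)
    if (!is.null(s$clamp)) U[s$clamp$node, ] <- 0
    spd <- sqrt(rowSums(U^2))
    max_speed <- max(max_speed, spd)
    disp <- dt * max(spd)
    if (disp > 2 * hmin)
      stop(sprintf("structure '%s': node displacement %.3g exceeds 2 grid cells; reduce dt",
                   s$label, disp))
    if (disp > 0.5 * hmin) warned <- TRUE
    s$points <- s$points + dt * U
    if (!is.null(s$clamp)) s$points[s$clamp$node, ] <- s$clamp$fixed_position
    state$structures[[i]] <- s
  }
  div_uv <- divergence(grid, fl$u, fl$v)
  state$fields <- fl
  state$time <- state$time + dt
  state$step <- state$step + 1L
  state$diag <- list(dt = dt, max_speed = max_speed,
                     div_max = max(abs(div_uv)),
                     removed_means = fl$removed_means,
                     cfl_warning = warned)
  state
}

#' Run an immersed boundary Stokes simulation
#'
#' Executes the explicit time loop: Lagrangian forces, spreading, the three
#' periodic Poisson solves, velocity interpolation and the forward-Euler
#' position update, until the configured stopping rule fires. Per-step
#' diagnostics (maximum node speed, discrete divergence max-norm, removed
#' Poisson means, and per-closed-structure radius extrema and enclosed area
#' about its diagnostic center) are collected in a data frame.
#'
#' @param config a [sim_config()].
#' @param centers optional list of length-2 centers, one per structure,
#'   about which radius extrema are measured for closed structures
#'   (default: the origin for each).
#' @param out_dir optional directory; when given, structure trajectories,
#'   the diagnostics table and field snapshots are written there as CSV.
#' @param snapshot_every stride (in steps) for keeping structure position
#'   snapshots in memory and, with \code{out_dir}, writing field CSVs.
#' @return object of class \code{"ib_sim"}: the final state, diagnostics
#'   data frame, snapshots, and convergence information.
#' @export
ib_run <- function(config, centers = NULL, out_dir = NULL,
                   snapshot_every = Inf) {
  grid <- config$grid
  ns <- length(config$structures)
  if (is.null(centers)) centers <- rep(list(c(0, 0)), ns)
  state <- new_state(config)
  cap <- if (!is.null(config$n_steps)) config$n_steps else config$max_steps
  diag_rows <- vector("list", 64)
  snapshots <- list(list(time = 0, structures = lapply(state$structures, `[[`, "points")))
  converged <- FALSE
  step_in_run <- 0L
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  repeat {
    if (!is.null(config$n_steps) && step_in_run >= config$n_steps) break
    if (!is.null(config$t_end) && state$time >= config$t_end - 1e-15) break
    if (step_in_run >= config$max_steps) break
    state <- ib_step(state, config)
    step_in_run <- step_in_run + 1L
    row <- c(step = state$step, time = state$time, dt = state$diag$dt,
             max_speed = state$diag$max_speed, div_max = state$diag$div_max,
             removed_mean_p = unname(state$diag$removed_means["p"]),
             removed_mean_u = unname(state$diag$removed_means["u"]),
             removed_mean_v = unname(state$diag$removed_means["v"]))
    for (i in seq_len(ns)) {
      s <- state$structures[[i]]
      if (s$topology == "closed") {
        re <- radius_extrema(s, centers[[i]])
        extra <- c(re["r_min"], re["r_max"], area = enclosed_area(s))
      } else {
        extra <- c(r_min = NA_real_, r_max = NA_real_, area = NA_real_)
      }
      names(extra) <- paste0(c("r_min_", "r_max_", "area_"), i)
      row <- c(row, extra)
    }
    if (step_in_run > length(diag_rows))
      diag_rows <- c(diag_rows, vector("list", length(diag_rows)))
    diag_rows[[step_in_run]] <- row
    if (is.finite(snapshot_every) && state$step %% snapshot_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <-
        list(time = state$time, structures = lapply(state$structures, `[[`, "points"))
      if (!is.null(out_dir)) write_field_snapshots(state, config, out_dir)
    }
    if (!is.null(config$tol_speed) && state$diag$max_speed < config$tol_speed) {
      converged <- TRUE
      break
    }
  }
  diagnostics <- as.data.frame(do.call(rbind, diag_rows[seq_len(step_in_run)]))
  sim <- structure(list(config = config, state = state, centers = centers,
                        diagnostics = diagnostics, snapshots = snapshots,
                        converged = converged, steps = step_in_run),
                   class = "ib_sim")
  if (!is.null(out_dir)) {
    write_trajectories(sim, out_dir)
    utils::write.csv(diagnostics, file.path(out_dir, paste0(config$name, "_diagnostics.csv")),
                     row.names = FALSE)
  }
  sim
}

write_field_snapshots <- function(state, config, out_dir) {
  if (is.null(state$fields)) return(invisible(NULL))
  for (nm in c("u", "v", "p", "fx", "fy")) {
    fn <- file.path(out_dir, sprintf("%s_%s_%06d.csv", config$name, nm, state$step))
    # rows = y index, per the snapshot file convention
    utils::write.table(t(state$fields[[nm]]), fn, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}

write_trajectories <- function(sim, out_dir) {
  ns <- length(sim$config$structures)
  for (i in seq_len(ns)) {
    rows <- lapply(seq_along(sim$snapshots), function(j) {
      sn <- sim$snapshots[[j]]
      P <- sn$structures[[i]]
      data.frame(step = j - 1L, time = sn$time, k = seq_len(nrow(P)) - 1L,
                 x = P[, 1], y = P[, 2])
    })
    fn <- file.path(out_dir, sprintf("%s_structure%d_trajectory.csv",
                                     sim$config$name, i))
    utils::write.csv(do.call(rbind, rows), fn, row.names = FALSE)
  }
  invisible(NULL)
}

#' @export
print.ib_sim <- function(x, ...) {
  cat(sprintf("Immersed boundary Stokes simulation '%s'\n", x$config$name))
  cat(sprintf("  %d structures on a %d x %d periodic grid, mu = %g\n",
              length(x$config$structures), x$config$grid$nx, x$config$grid$ny,
              x$config$mu))
  cat(sprintf("  %d steps to t = %.6g; %s\n", x$steps, x$state$time,
              if (x$converged) sprintf("converged (max node speed < %g)", x$config$tol_speed)
              else "stopping rule: step/time limit"))
  if (x$steps > 0)
    cat(sprintf("  final max node speed %.3e, divergence max-norm %.3e\n",
                x$diagnostics$max_speed[x$steps], x$diagnostics$div_max[x$steps]))
  invisible(x)
}

#' @export
summary.ib_sim <- function(object, ...) {
  d <- object$diagnostics
  cat(sprintf("'%s': %d steps, t = %.6g, converged = %s\n",
              object$config$name, object$steps, object$state$time, object$converged))
  for (i in seq_along(object$config$structures)) {
    s <- object$state$structures[[i]]
    if (s$topology == "closed") {
      re <- radius_extrema(s, object$centers[[i]])
      a0 <- d[[paste0("area_", i)]][1]
      a1 <- enclosed_area(s)
      cat(sprintf("  structure %d ('%s'): r_min = %.4f, r_max = %.4f, area drift %.3f%%\n",
                  i, s$label, re["r_min"], re["r_max"], 100 * (a1 - a0) / a0))
    } else {
      cat(sprintf("  structure %d ('%s'): open filament, free end at (%.4f, %.4f)\n",
                  i, s$label, s$points[1, 1], s$points[1, 2]))
    }
  }
  invisible(object)
}

#' Plot simulation diagnostics and structure shapes
#'
#' Two panels: the radius-extrema traces of closed structures against time,
#' and the initial (dashed) versus final (solid) structure shapes.
#'
#' @param x an \code{ib_sim} object.
#' @param ... passed to \code{plot}.
#' @export
plot.ib_sim <- function(x, ...) {
  d <- x$diagnostics
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  closed <- which(vapply(x$config$structures, function(s) s$topology == "closed",
                         logical(1)))
  if (length(closed) && nrow(d)) {
    i <- closed[1]
    graphics::matplot(d$time, cbind(d[[paste0("r_min_", i)]], d[[paste0("r_max_", i)]]),
                      type = "l", lty = 1, col = c("steelblue", "firebrick"),
                      xlab = "time", ylab = "radius", main = "radius extrema", ...)
    graphics::legend("right", c("r_min", "r_max"), lty = 1,
                     col = c("steelblue", "firebrick"), bty = "n")
  } else {
    graphics::plot(d$time, d$max_speed, type = "l", log = "y",
                   xlab = "time", ylab = "max node speed", main = "relaxation")
  }
  g <- x$config$grid
  graphics::plot(NA, xlim = c(g$x0, g$x1), ylim = c(g$y0, g$y1), asp = 1,
                 xlab = "x", ylab = "y", main = "structures")
  for (i in seq_along(x$state$structures)) {
    P0 <- x$snapshots[[1]]$structures[[i]]
    P1 <- x$state$structures[[i]]$points
    cl <- x$state$structures[[i]]$topology == "closed"
    if (cl) { P0 <- rbind(P0, P0[1, ]); P1 <- rbind(P1, P1[1, ]) }
    graphics::lines(P0, lty = 2, col = i + 1)
    graphics::lines(P1, lty = 1, col = i + 1)
  }
  invisible(x)
}
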