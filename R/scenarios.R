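#' Star-shaped closed membrane
#'
#' Eight-lobed perturbed circle sampled at equally spaced polar angles,
#' \code{rho(theta) = 0.6 + 0.3 sin(8 theta)}, with unstretched (rest)
#' radius \code{r_rest}. Stretched well beyond its rest length everywhere,
#' the string relaxes toward a circle under tension alone (\code{cb = 0}).
#'
#' @param Nb number of boundary nodes (>= 16).
#' @param r_rest unstretched radius; sets \code{ds = 2*pi*r_rest/Nb}.
#' @param cs stiffness coefficient.
#' @return closed [ib_structure()].
#' @export
make_star <- function(Nb = 160, r_rest = 0.3, cs = 100) {
  Nb <- as.integer(Nb)
  if (Nb < 16L) stop("'Nb' must be >= 16")
  th <- 2 * pi * (seq_len(Nb) - 1) / Nb
  rho <- 0.6 + 0.3 * sin(8 * th)
  ib_structure(cbind(rho * cos(th), rho * sin(th)), topology = "closed",
               ds = 2 * pi * r_rest / Nb, cs = cs, cb = 0, label = "star")
}

#' Quarter-circle filament clamped at the wall
#'
#' Open filament initialized as the quarter arc
#' \code{(r cos(theta), |r sin(theta)|) - (r, 0)} for \code{theta} in
#' \code{[0, pi/2]}: the fixed end sits at the origin on the bottom wall and
#' the free end at \code{(-r, r)}. Nodes are numbered from the free end
#' (first) to the clamped end (last); the clamp pins the last node at the
#' origin and carries the prescribed wall-tangent datum used by the clamped
#' curvature condition. The arc is unstretched at t = 0 (chords are shorter
#' than \code{ds}), so initially only bending forces act.
#'
#' @param Nb number of nodes (>= 8).
#' @param r arc radius; \code{ds = (pi*r/2)/(Nb - 1)}.
#' @param cs,cb stiffness and bending coefficients.
#' @param clamp_tangent length-2 clamp tangent datum (default \code{(-1, 0)}).
#' @return open, clamped [ib_structure()].
#' @export
make_filament_arc <- function(Nb = 30, r = 0.25, cs = 2, cb = 0.001,
                              clamp_tangent = c(-1, 0)) {
  Nb <- as.integer(Nb)
  if (Nb < 8L) stop("'Nb' must be >= 8")
  # first node = free end (theta = pi/2), last node = fixed end (theta = 0)
  th <- (pi / 2) * rev(seq_len(Nb) - 1) / (Nb - 1)
  pts <- cbind(r * cos(th) - r, abs(r * sin(th)))
  ib_structure(pts, topology = "open", ds = (pi * r / 2) / (Nb - 1),
               cs = cs, cb = cb,
               clamp = list(fixed_position = c(0, 0), tangent = clamp_tangent),
               label = "filament")
}

#' Circular closed membrane at its equilibrium state
#'
#' Uniformly sampled circle with \code{ds = 2*pi*radius/Nb}, so the initial
#' chord/arc stretch is slightly below 1 and the one-sided tension is
#' exactly zero: the membrane exerts no force until the flow deforms it.
#'
#' @param Nb number of nodes (>= 16).
#' @param radius circle radius.
#' @param center length-2 center.
#' @param cs stiffness coefficient.
#' @param cb bending coefficient (default 0: a pure string).
#' @return closed [ib_structure()].
#' @export
make_circle <- function(Nb = 100, radius = 0.3, center = c(0, 1),
                        cs = 0.01, cb = 0) {
  Nb <- as.integer(Nb)
  if (Nb < 16L) stop("'Nb' must be >= 16")
  th <- 2 * pi * (seq_len(Nb) - 1) / Nb
  ib_structure(cbind(center[1] + radius * cos(th), center[2] + radius * sin(th)),
               topology = "closed", ds = 2 * pi * radius / Nb,
               cs = cs, cb = cb, label = "circle")
}

#' Minimum and maximum node radius about a center
#'
#' The instantaneous radius extrema of a closed structure: minimum and
#' maximum Euclidean node distance from the given center.
#'
#' @param struct a closed [ib_structure()].
#' @param center length-2 reference point (origin by default).
#' @return named vector \code{c(r_min, r_max)}.
#' @export
radius_extrema <- function(struct, center = c(0, 0)) {
  if (struct$topology != "closed")
    stop("radius extrema are defined for closed structures")
  r <- sqrt((struct$points[, 1] - center[1])^2 + (struct$points[, 2] - center[2])^2)
  c(r_min = min(r), r_max = max(r))
}

#' Enclosed polygon area of a closed structure
#'
#' Shoelace area of the node loop, positive for counterclockwise
#' orientation. Used to monitor the small area leakage inherent to
#' regularized-delta coupling.
#'
#' @param struct a closed [ib_structure()].
#' @return signed area (positive when counterclockwise).
#' @export
enclosed_area <- function(struct) {
  if (struct$topology != "closed")
    stop("enclosed area is defined for closed structures")
  X <- struct$points
  n <- nrow(X)
  i2 <- c(2:n, 1L)
  sum(X[, 1] * X[i2, 2] - X[i2, 1] * X[, 2]) / 2
}

scenario_names <- c("star_relaxation", "bending_filament", "filament_circle")

#' Ready-made scenario configurations
#'
#' Returns the full [sim_config()] for one of the three packaged scenarios:
#' \describe{
#'   \item{star_relaxation}{A tense star-shaped string (Nb = 160, rest
#'     radius 0.3, cs = 100, cb = 0) relaxing to a circle on a 64 x 64 grid
#'     over \code{(-1,1)^2}, mu = 1. The default time step starts at h^2/16
#'     (the largest power-of-two fraction of h^2 keeping the initial node
#'     displacement under half a grid cell during the very stiff start) and
#'     relaxes to h^2/4 at t = 0.05 once the fast transient has decayed.
#'     The run stops at equilibrium, when the maximum node speed drops
#'     below \code{2e-3} — just above the residual drift speed that the
#'     slow area leakage of regularized-delta coupling sustains
#'     indefinitely.}
#'   \item{bending_filament}{A clamped quarter-circle filament (Nb = 30,
#'     radius 0.25, cs = 2, cb = 0.001) swinging back to straight on a
#'     64 x 64 grid over \code{(-1,1) x (0,2)}, mu = 1, dt = 4e-4.}
#'   \item{filament_circle}{The same filament plus a passive circular
#'     membrane (Nb = 100, radius 0.3, center (0,1), cs = 0.01, cb = 0 — a
#'     pure string, so its nodes stay free to rotate) deformed by the
#'     induced flow; dt = 5e-4.}
#' }
#' Diagnostic centers: the origin for the star, the circle's initial center
#' for the passive membrane.
#'
#' @param name one of \code{"star_relaxation"}, \code{"bending_filament"},
#'   \code{"filament_circle"}.
#' @param ... overrides passed to [sim_config()] (e.g. \code{n_steps},
#'   \code{tol_speed}).
#' @return list with \code{config} (a [sim_config()]) and \code{centers}.
#' @export
ib_scenario <- function(name = scenario_names, ...) {
  name <- match.arg(name)
  dots <- list(...)
  build <- function(defaults) {
    defaults[names(dots)] <- dots
    do.call(sim_config, defaults)
  }
  if (name == "star_relaxation") {
    grid <- periodic_grid(64, 64, c(-1, 1, -1, 1))
    h2 <- grid$hx^2
    cfg <- build(list(grid = grid, structures = list(make_star()),
                      mu = 1, dt = h2 / 16, tol_speed = 2e-3,
                      dt_schedule = data.frame(t = c(0, 0.05),
                                               dt = c(h2 / 16, h2 / 4)),
                      max_steps = 100000L, name = name))
    return(list(config = cfg, centers = list(c(0, 0))))
  }
  if (name == "bending_filament") {
    grid <- periodic_grid(64, 64, c(-1, 1, 0, 2))
    cfg <- build(list(grid = grid, structures = list(make_filament_arc()),
                      mu = 1, dt = 4e-4, t_end = 0.032, name = name))
    return(list(config = cfg, centers = list(c(0, 0))))
  }
  grid <- periodic_grid(64, 64, c(-1, 1, 0, 2))
  cfg <- build(list(grid = grid,
                    structures = list(make_filament_arc(),
                                      make_circle()),
                    mu = 1, dt = 5e-4, t_end = 0.0165, name = name))
  list(config = cfg, centers = list(c(0, 0), c(0, 1)))
}

#' Load a scenario configuration from a YAML file
#'
#' Reads a validated YAML description of a simulation. Top-level keys:
#' \code{scenario} (optional packaged scenario name to start from) and/or
#' \code{grid} (\code{nx, ny, extents}), \code{mu}, \code{dt},
#' \code{n_steps}, \code{t_end}, \code{tol_speed}, \code{dt_schedule},
#' \code{name}, and \code{structures}: a list of records with \code{kind}
#' (\code{star}, \code{filament_arc}, \code{circle}) and that generator's
#' parameters. Unknown keys are rejected with a message naming the key.
#'
#' @param path YAML file path.
#' @return list with \code{config} and \code{centers}, as [ib_scenario()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) {
    if (!y$scenario %in% scenario_names)
      stop(sprintf("unknown scenario '%s'; known: %s", y$scenario,
                   paste(scenario_names, collapse = ", ")))
    extra <- setdiff(names(y), c("scenario", "n_steps", "t_end", "tol_speed",
                                 "dt", "name"))
    if (length(extra))
      stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
    return(do.call(ib_scenario, c(list(name = y$scenario),
                                  y[setdiff(names(y), "scenario")])))
  }
  allowed <- c("grid", "mu", "dt", "n_steps", "t_end", "tol_speed",
               "dt_schedule", "name", "structures")
  extra <- setdiff(names(y), allowed)
  if (length(extra))
    stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  if (is.null(y$grid)) stop("config requires 'grid' (nx, ny, extents)")
  if (is.null(y$structures) || !length(y$structures))
    stop("config requires at least one entry under 'structures'")
  grid <- periodic_grid(y$grid$nx, y$grid$ny, unlist(y$grid$extents))
  centers <- list()
  structs <- list()
  for (i in seq_along(y$structures)) {
    rec <- y$structures[[i]]
    kind <- rec$kind
    if (is.null(kind)) stop(sprintf("structures[%d]: missing 'kind'", i))
    rec$kind <- NULL
    ctr <- c(0, 0)
    s <- switch(kind,
      star = do.call(make_star, rec),
      filament_arc = do.call(make_filament_arc, rec),
      circle = {
        if (!is.null(rec$center)) rec$center <- unlist(rec$center)
        st <- do.call(make_circle, rec)
        ctr <- if (!is.null(rec$center)) rec$center else c(0, 1)
        st
      },
      stop(sprintf("structures[%d]: unknown kind '%s'", i, kind))
    )
    structs[[i]] <- s
    centers[[i]] <- ctr
  }
  args <- y[intersect(names(y), c("mu", "dt", "n_steps", "t_end", "tol_speed",
                                  "dt_schedule", "name"))]
  cfg <- do.call(sim_config, c(list(grid = grid, structures = structs), args))
  list(config = cfg, centers = centers)
}
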