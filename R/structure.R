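#' Lagrangian elastic structure
#'
#' An immersed boundary is an ordered chain of massless material points
#' carrying an elastic energy with a stretching and a bending term.
#' Tensions live on a staggered grid of segment midpoints; bending forces
#' live on the nodes. Open chains (filaments) are numbered from the free end
#' (first row) to the fixed end (last row), and a clamp record pins the
#' fixed end and supplies the prescribed wall tangent used by the clamped
#' curvature condition.
#'
#' The tension is one-sided: a segment stretched beyond its rest length
#' \code{ds} pulls with \code{cs * (stretch - 1)}, while a slack segment
#' carries exactly zero tension (strings do not push).
#'
#' @param points \code{n x 2} numeric matrix of node positions (n >= 4).
#' @param topology \code{"closed"} (last node connects back to the first) or
#'   \code{"open"}.
#' @param ds unstretched arclength spacing between neighboring nodes.
#' @param cs stiffness (stretching) coefficient, force per unit strain.
#' @param cb bending coefficient.
#' @param clamp for open chains, a list with \code{fixed_position} (length-2)
#'   and \code{tangent} (length-2, normalized internally); the clamped node
#'   is always the last one. \code{NULL} for free or closed structures.
#' @param label free-text identifier used in diagnostics and error messages.
#' @return object of class \code{"ib_structure"}.
#' @examples
#' th <- 2 * pi * (0:31) / 32
#' circ <- ib_structure(cbind(0.5 * cos(th), 0.5 * sin(th)),
#'                      topology = "closed", ds = 2 * pi * 0.3 / 32, cs = 1)
#' @export
ib_structure <- function(points, topology = c("closed", "open"),
                         ds, cs = 0, cb = 0, clamp = NULL, label = "structure") {
  topology <- match.arg(topology)
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 4L)
    stop("'points' must be an n x 2 matrix with n >= 4")
  if (!all(is.finite(points))) stop("'points' contains non-finite values")
  if (!is.numeric(ds) || length(ds) != 1L || ds <= 0)
    stop("'ds' must be a positive scalar")
  if (cs < 0) stop("'cs' must be >= 0")
  if (cb < 0) stop("'cb' must be >= 0")
  if (!is.null(clamp)) {
    if (topology != "open") stop("a clamp is only meaningful for open topology")
    if (is.null(clamp$fixed_position) || length(clamp$fixed_position) != 2L)
      stop("clamp$fixed_position must be a length-2 vector")
    if (is.null(clamp$tangent) || length(clamp$tangent) != 2L)
      stop("clamp$tangent must be a length-2 vector")
    nt <- sqrt(sum(clamp$tangent^2))
    if (nt == 0) stop("clamp$tangent must be nonzero")
    clamp$tangent <- clamp$tangent / nt
    clamp$node <- nrow(points)  # fixed end is the last node by convention
  }
  structure(list(points = points, topology = topology, ds = ds,
                 cs = cs, cb = cb, clamp = clamp, label = label),
            class = "ib_structure")
}

#' @export
print.ib_structure <- function(x, ...) {
  cat(sprintf("Immersed boundary '%s': %s chain of %d nodes, ds = %g, cs = %g, cb = %g%s\n",
              x$label, x$topology, nrow(x$points), x$ds, x$cs, x$cb,
              if (!is.null(x$clamp)) ", clamped at last node" else ""))
  invisible(x)
}

n_segments <- function(struct) {
  if (struct$topology == "closed") nrow(struct$points) else nrow(struct$points) - 1L
}

# segment vectors X_{k+1} - X_k (with wrap for closed chains)
segment_vectors <- function(struct) {
  X <- struct$points
  n <- nrow(X)
  if (struct$topology == "closed") {
    X[c(2:n, 1L), , drop = FALSE] - X
  } else {
    X[-1L, , drop = FALSE] - X[-n, , drop = FALSE]
  }
}

#' Per-segment stretch ratios
#'
#' Ratio of current segment length to the rest spacing, one value per
#' segment midpoint: \code{|X_{k+1} - X_k| / ds}. Closed chains include the
#' wrap-around segment. Stretch 1 is the rest state; values below 1 mean a
#' slack segment.
#'
#' @param struct an [ib_structure()].
#' @return numeric vector, one entry per segment.
#' @export
segment_stretch <- function(struct) {
  dX <- segment_vectors(struct)
  sqrt(rowSums(dX^2)) / struct$ds
}

#' Per-segment tension magnitudes
#'
#' One-sided elastic tension at each segment midpoint:
#' \code{T = cs * (stretch - 1)} where the stretch is at least 1, and
#' exactly 0 for slack segments.
#'
#' @param struct an [ib_structure()].
#' @return numeric vector of tensions, one per segment.
#' @export
tension <- function(struct) {
  s <- segment_stretch(struct)
  ifelse(s >= 1, struct$cs * (s - 1), 0)
}

#' Stretching (tension) force density at the nodes
#'
#' Difference of tension times unit tangent across the two midpoints
#' adjacent to each node, divided by \code{ds}. On a closed chain all nodes
#' are interior and the forces telescope, so the total stretching force is
#' exactly zero. On an open chain the two end nodes take the natural
#' one-sided terms (the boundary terms of the variational derivative), which
#' preserves the zero total.
#'
#' @param struct an [ib_structure()].
#' @return \code{n x 2} matrix of force densities per unit unstretched
#'   arclength.
#' @export
stretching_force <- function(struct) {
  X <- struct$points
  n <- nrow(X)
  ds <- struct$ds
  dX <- segment_vectors(struct)
  len <- sqrt(rowSums(dX^2))
  if (struct$cs > 0 && any(len == 0))
    stop(sprintf("structure '%s': zero-length segment at index %d, tangent undefined",
                 struct$label, which(len == 0)[1]))
  Tm <- tension(struct)
  # tension times unit tangent on each midpoint; slack segments contribute 0
  tt <- dX
  pos <- len > 0
  tt[pos, ] <- dX[pos, , drop = FALSE] * (Tm[pos] / len[pos])
  tt[!pos, ] <- 0
  Fs <- matrix(0, n, 2)
  if (struct$topology == "closed") {
    prev <- c(n, 1:(n - 1))
    Fs <- (tt - tt[prev, , drop = FALSE]) / ds
  } else {
    Fs[1, ] <- tt[1, ] / ds
    if (n > 2) Fs[2:(n - 1), ] <- (tt[2:(n - 1), , drop = FALSE] -
                                     tt[1:(n - 2), , drop = FALSE]) / ds
    Fs[n, ] <- -tt[n - 1, ] / ds
  }
  Fs
}

#' Bending force density at the nodes
#'
#' Fourth-difference penalty on curvature: interior nodes carry
#' \code{-cb D+D-(Dss X)} built from second differences of positions. On a
#' closed chain the stencil is the periodic fourth difference. On an open
#' filament the staggered boundary closures are: zero curvature at the free
#' end, a third-difference form for the free-end force, and at the clamped
#' end a curvature datum formed from the prescribed clamp tangent,
#' \code{(Dss X)_N = [tangent - (X_N - X_{N-1})/ds] / (ds/2)}, which couples
#' the wall orientation into the force one node in. The clamped node itself
#' is pinned, so its own force entry is zero.
#'
#' @param struct an [ib_structure()]; open structures with \code{cb > 0}
#'   must carry a clamp.
#' @return \code{n x 2} matrix of force densities.
#' @export
bending_force <- function(struct) {
  X <- struct$points
  n <- nrow(X)
  ds <- struct$ds
  cb <- struct$cb
  if (cb == 0) return(matrix(0, n, 2))
  if (struct$topology == "closed") {
    i1 <- c(2:n, 1L); i2 <- i1[c(2:n, 1L)]
    m1 <- c(n, 1:(n - 1)); m2 <- m1[c(n, 1:(n - 1))]
    Fb <- -(cb / ds^4) * (X[i2, , drop = FALSE] - 4 * X[i1, , drop = FALSE] +
                            6 * X - 4 * X[m1, , drop = FALSE] + X[m2, , drop = FALSE])
    return(Fb)
  }
  if (is.null(struct$clamp))
    stop(sprintf("structure '%s': open chain with cb > 0 requires a clamp", struct$label))
  # curvature vector (Dss X) on nodes, with the staggered end closures
  D2 <- matrix(0, n, 2)
  if (n > 2) D2[2:(n - 1), ] <- (X[3:n, , drop = FALSE] - 2 * X[2:(n - 1), , drop = FALSE] +
                                   X[1:(n - 2), , drop = FALSE]) / ds^2
  D2[n, ] <- (struct$clamp$tangent - (X[n, ] - X[n - 1, ]) / ds) / (0.5 * ds)
  Fb <- matrix(0, n, 2)
  Fb[2:(n - 1), ] <- -(cb / ds^2) * (D2[3:n, , drop = FALSE] -
                                       2 * D2[2:(n - 1), , drop = FALSE] +
                                       D2[1:(n - 2), , drop = FALSE])
  # free end: third-difference closure built from the two nearest curvatures
  Fb[1, ] <- -(cb / ds^2) * (D2[3, ] - D2[2, ])
  Fb[n, ] <- 0  # pinned node, never advanced
  Fb
}

#' Total Lagrangian force on a structure
#'
#' Sum of [stretching_force()] and [bending_force()], with the midpoint
#' tensions recorded for diagnostics.
#'
#' @param struct an [ib_structure()].
#' @return object of class \code{"lagrangian_forces"}: list with \code{F}
#'   (\code{n x 2} force densities), \code{tension} (per-midpoint), and the
#'   originating structure.
#' @export
total_force <- function(struct) {
  Fs <- stretching_force(struct)
  Fb <- bending_force(struct)
  structure(list(F = Fs + Fb, tension = tension(struct), structure = struct),
            class = "lagrangian_forces")
}

#' @export
print.lagrangian_forces <- function(x, ...) {
  cat(sprintf("Lagrangian forces on '%s': max |F| = %.4g, max tension = %.4g\n",
              x$structure$label, max(sqrt(rowSums(x$F^2))),
              if (length(x$tension)) max(x$tension) else 0))
  invisible(x)
}
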