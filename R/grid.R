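#' Periodic Eulerian grid
#'
#' Constructs the fixed Cartesian grid on which all Eulerian fields (velocity
#' components, pressure, force density) are sampled. The domain
#' \code{[x0, x1) x [y0, y1)} is periodic in both directions with the
#' half-open convention: node \code{i} (0-based) sits at \code{x0 + i*hx} and
#' the line \code{x = x1} is identified with \code{x = x0}. All fields are
#' stored as \code{nx x ny} matrices whose row index runs over x and column
#' index over y.
#'
#' @param nx,ny number of cells (= nodes) in x and y; at least 8 each.
#' @param extents numeric length-4 vector \code{c(x0, x1, y0, y1)}.
#' @return an object of class \code{"periodic_grid"}: a list with \code{nx},
#'   \code{ny}, the extents, spacings \code{hx}, \code{hy} and node coordinate
#'   vectors \code{x}, \code{y}.
#' @examples
#' g <- periodic_grid(64, 64, c(-1, 1, -1, 1))
#' g$hx  # 2/64 = 0.03125
#' @export
periodic_grid <- function(nx, ny, extents) {
  if (length(extents) != 4L || !is.numeric(extents) || anyNA(extents))
    stop("'extents' must be numeric c(x0, x1, y0, y1)")
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || nx < 8L) stop("'nx' must be an integer >= 8")
  if (is.na(ny) || ny < 8L) stop("'ny' must be an integer >= 8")
  x0 <- extents[1]; x1 <- extents[2]; y0 <- extents[3]; y1 <- extents[4]
  if (x1 <= x0) stop("'extents': x1 must exceed x0")
  if (y1 <= y0) stop("'extents': y1 must exceed y0")
  hx <- (x1 - x0) / nx
  hy <- (y1 - y0) / ny
  structure(list(
    nx = nx, ny = ny, x0 = x0, x1 = x1, y0 = y0, y1 = y1,
    hx = hx, hy = hy,
    x = x0 + (seq_len(nx) - 1) * hx,
    y = y0 + (seq_len(ny) - 1) * hy
  ), class = "periodic_grid")
}

#' @export
print.periodic_grid <- function(x, ...) {
  cat(sprintf("Periodic grid: %d x %d on [%g, %g) x [%g, %g), h = (%g, %g)\n",
              x$nx, x$ny, x$x0, x$x1, x$y0, x$y1, x$hx, x$hy))
  invisible(x)
}

check_field <- function(grid, f, name = "field") {
  if (!is.matrix(f) || nrow(f) != grid$nx || ncol(f) != grid$ny)
    stop(sprintf("'%s' must be a %d x %d matrix matching the grid",
                 name, grid$nx, grid$ny))
  if (!all(is.finite(f))) stop(sprintf("'%s' contains non-finite values", name))
  invisible(f)
}

# circular shift helpers: index vectors for f[i+1], f[i-1] with wrap
shift_up <- function(n) c(2:n, 1L)      # i + 1
shift_dn <- function(n) c(n, 1:(n - 1)) # i - 1

#' Central-difference gradient of a scalar field
#'
#' Second-order central differences with periodic index wrap:
#' \code{(f[i+1,j] - f[i-1,j]) / (2 hx)} and analogously in y. Used to form
#' the pressure gradient in the momentum balance and (via [divergence()]) the
#' right-hand side of the pressure Poisson equation.
#'
#' @param grid a [periodic_grid()].
#' @param f scalar field (\code{nx x ny} matrix).
#' @return list with components \code{x} and \code{y}, each an
#'   \code{nx x ny} matrix.
#' @export
central_gradient <- function(grid, f) {
  check_field(grid, f, "f")
  up <- shift_up(grid$nx); dn <- shift_dn(grid$nx)
  gx <- (f[up, , drop = FALSE] - f[dn, , drop = FALSE]) / (2 * grid$hx)
  up <- shift_up(grid$ny); dn <- shift_dn(grid$ny)
  gy <- (f[, up, drop = FALSE] - f[, dn, drop = FALSE]) / (2 * grid$hy)
  list(x = gx, y = gy)
}

#' Central-difference divergence of a vector field
#'
#' Periodic central-difference divergence \code{d(vx)/dx + d(vy)/dy}. On a
#' periodic grid the result telescopes: its sum over all nodes is zero to
#' round-off for any input.
#'
#' @param grid a [periodic_grid()].
#' @param vx,vy the two field components (\code{nx x ny} matrices).
#' @return scalar field matrix.
#' @export
divergence <- function(grid, vx, vy) {
  check_field(grid, vx, "vx"); check_field(grid, vy, "vy")
  up <- shift_up(grid$nx); dn <- shift_dn(grid$nx)
  dx <- (vx[up, , drop = FALSE] - vx[dn, , drop = FALSE]) / (2 * grid$hx)
  up <- shift_up(grid$ny); dn <- shift_dn(grid$ny)
  dy <- (vy[, up, drop = FALSE] - vy[, dn, drop = FALSE]) / (2 * grid$hy)
  dx + dy
}

#' Five-point Laplacian with periodic wrap
#'
#' The standard second-order stencil
#' \code{(f[i-1,j] - 2 f[i,j] + f[i+1,j])/hx^2 + (f[i,j-1] - 2 f[i,j] +
#' f[i,j+1])/hy^2}. This is the discrete operator whose inverse
#' [poisson_solve()] applies; it annihilates constants, so the periodic
#' system is singular with the constant mode in its null space.
#'
#' @param grid a [periodic_grid()].
#' @param f scalar field matrix.
#' @return scalar field matrix.
#' @export
laplacian_5pt <- function(grid, f) {
  check_field(grid, f, "f")
  upx <- shift_up(grid$nx); dnx <- shift_dn(grid$nx)
  upy <- shift_up(grid$ny); dny <- shift_dn(grid$ny)
  (f[upx, , drop = FALSE] - 2 * f + f[dnx, , drop = FALSE]) / grid$hx^2 +
    (f[, upy, drop = FALSE] - 2 * f + f[, dny, drop = FALSE]) / grid$hy^2
}
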