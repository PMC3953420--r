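#' Exact direct solver for the periodic 5-point Poisson system
#'
#' Solves \code{laplacian_5pt(phi) = rhs} on the periodic grid by spectral
#' diagonalization: the 5-point stencil is diagonal in the discrete Fourier
#' basis with eigenvalues
#' \deqn{\lambda_{kl} = \frac{2\cos(2\pi k/n_x) - 2}{h_x^2}
#'                    + \frac{2\cos(2\pi l/n_y) - 2}{h_y^2},}
#' so one forward and one inverse FFT give the exact solution of the linear
#' system to round-off.
#'
#' The periodic operator is singular: constants lie in its null space and a
#' solution exists only for zero-mean right-hand sides. Any input is
#' projected to zero mean before solving and the removed mean is reported
#' (a nonzero removed mean on a velocity equation signals net unbalanced
#' force over the box). The free constant in the solution is fixed by the
#' zero-mean gauge.
#'
#' The \code{"wide"} stencil variant inverts the composition of the
#' central-difference divergence and gradient operators (a Laplacian on a
#' 2h stencil), which is what the pressure equation needs on this collocated
#' grid for the resulting velocity field to be discretely divergence-free:
#' with \code{div(grad p) = div f} satisfied by the same central operators
#' that assemble the momentum right-hand sides, \code{div(u, v)} vanishes
#' identically. The wide operator has extra null modes — the four
#' grid-Nyquist checkerboards, which the central gradient cannot see — and
#' these are projected out of the right-hand side along with the mean.
#'
#' @param grid a [periodic_grid()].
#' @param rhs scalar field matrix.
#' @param stencil \code{"5pt"} (default) or \code{"wide"}; see Details.
#' @return list of class \code{"poisson_result"}: \code{solution} (zero-mean
#'   matrix), \code{removed_mean}, and \code{residual_norm}, the max-norm of
#'   the chosen discrete Laplacian of the solution minus the adjusted
#'   (projected) right-hand side.
#' @export
poisson_solve <- function(grid, rhs, stencil = c("5pt", "wide")) {
  stencil <- match.arg(stencil)
  check_field(grid, rhs, "rhs")
  removed_mean <- mean(rhs)
  kx <- seq_len(grid$nx) - 1; ky <- seq_len(grid$ny) - 1
  if (stencil == "5pt") {
    lam_x <- (2 * cos(2 * pi * kx / grid$nx) - 2) / grid$hx^2
    lam_y <- (2 * cos(2 * pi * ky / grid$ny) - 2) / grid$hy^2
  } else {
    lam_x <- (2 * cos(4 * pi * kx / grid$nx) - 2) / (4 * grid$hx^2)
    lam_y <- (2 * cos(4 * pi * ky / grid$ny) - 2) / (4 * grid$hy^2)
  }
  lam <- outer(lam_x, lam_y, `+`)
  ahat <- stats::fft(rhs)
  nz <- abs(lam) > 1e-12 * max(abs(lam))
  phihat <- ahat
  phihat[!nz] <- 0
  phihat[nz] <- ahat[nz] / lam[nz]
  N <- grid$nx * grid$ny
  phi <- Re(stats::fft(phihat, inverse = TRUE)) / N
  phi <- phi - mean(phi)
  # residual against the rhs restricted to the operator's range
  ahat[!nz] <- 0
  a_adj <- Re(stats::fft(ahat, inverse = TRUE)) / N
  lap <- if (stencil == "5pt") laplacian_5pt(grid, phi)
         else divergence(grid, central_gradient(grid, phi)$x,
                         central_gradient(grid, phi)$y)
  res <- max(abs(lap - a_adj))
  structure(list(solution = phi, removed_mean = removed_mean,
                 residual_norm = res, stencil = stencil),
            class = "poisson_result")
}

#' @export
print.poisson_result <- function(x, ...) {
  cat(sprintf("Periodic Poisson solution: removed mean %.3e, residual max-norm %.3e\n",
              x$removed_mean, x$residual_norm))
  invisible(x)
}
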