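#' Gradient/rotation (Helmholtz-style) split of a subspace's dynamics
#'
#' Within an activation subspace the dynamics are linear,
#' \code{dx/dt = M x + u} with \code{M} the effective system matrix
#' (\code{effective_jacobian} of the pattern). \code{M} splits exactly into
#' \code{M1 = diag(M)}, the expansion/contraction component carrying all of
#' the divergence (self-excitation minus leak per unit), and
#' \code{M2 = M - M1}, the zero-trace rotational component carried by the
#' excitatory-inhibitory loops. Because \code{beta2 != beta1} the loop part
#' of \code{M2} is not skew-symmetric as written, but the diagonal
#' coordinate change \code{Phi} that rescales each inhibitory coordinate by
#' \code{sqrt(beta1/beta2)} of its loop makes it so, with off-diagonal
#' magnitudes \code{sqrt(beta1*beta2)}; being diagonal, \code{Phi} leaves
#' \code{M1} untouched and preserves all eigenvalues.
#'
#' The transform exists only when the loop weights are uniform per
#' inhibitory unit and there are no excitatory-excitatory cross-connections
#' off the diagonal; otherwise \code{valid = FALSE} and the residual
#' asymmetry norm is reported.
#'
#' @param net a \code{wta_network}.
#' @param pattern non-empty binary n-vector.
#' @return An object of class \code{wta_helmholtz}: list with \code{M},
#'   \code{M1}, \code{M2}, \code{Phi} (diagonal matrix over active units),
#'   \code{M2_rot} (\code{Phi M2 Phi^-1}), \code{valid}, \code{residual}
#'   (norm of the symmetric part of \code{M2_rot}).
#' @examples
#' net <- build_wta(2, network_params(g_exc = 1, g_inh = 1))
#' hs <- helmholtz_split(net, c(1, 1, 1))
#' hs$M2_rot + t(hs$M2_rot)    # skew-symmetric: ~ 0
#' @export
helmholtz_split <- function(net, pattern) {
  stopifnot(inherits(net, "wta_network"), length(pattern) == net$n)
  pattern <- as.integer(pattern)
  act <- which(pattern == 1L)
  if (length(act) == 0L) stop("pattern is empty", call. = FALSE)
  M <- effective_jacobian(net, pattern)
  M1 <- diag(diag(M), nrow = nrow(M))
  M2 <- M - M1
  dimnames(M1) <- dimnames(M2) <- dimnames(M)

  types <- net$types[act]
  phi <- rep(1, length(act))
  valid <- TRUE
  # exc-exc off-diagonal coupling cannot be skew-symmetrized by a diagonal
  # transform (both entries are >= 0)
  exc_r <- which(types == "exc")
  off_ee <- M2[exc_r, exc_r, drop = FALSE]
  if (any(off_ee != 0)) valid <- FALSE
  if (any(M2[types == "inh", types == "inh", drop = FALSE] != 0)) valid <- FALSE
  for (r in which(types == "inh")) {
    j <- act[r]
    partners <- which(types == "exc" &
                        (M2[r, ] != 0 | M2[, r] != 0))
    if (length(partners) == 0L) next
    b1 <- -M2[partners, r]  # inhibitory -> excitatory
    b2 <- M2[r, partners]   # excitatory -> inhibitory
    if (any(b1 <= 0) || any(b2 <= 0)) { valid <- FALSE; next }
    ratios <- b1 / b2
    if (diff(range(ratios)) > 1e-8 * max(ratios)) valid <- FALSE
    phi[r] <- sqrt(stats::median(ratios))
  }
  Phi <- diag(phi, nrow = length(act))
  M2_rot <- Phi %*% M2 %*% solve(Phi)
  residual <- max(abs(M2_rot + t(M2_rot)))
  if (valid && residual > 1e-10) valid <- FALSE
  structure(list(M = M, M1 = M1, M2 = M2, Phi = Phi, M2_rot = M2_rot,
                 valid = valid, residual = residual, active = act),
            class = "wta_helmholtz")
}

#' @export
print.wta_helmholtz <- function(x, ...) {
  cat("Helmholtz split over", nrow(x$M), "active units:",
      if (x$valid) "skew-symmetrizing Phi found"
      else sprintf("no diagonal Phi (residual %.3g)", x$residual), "\n")
  cat("  divergence(M) =", format(sum(diag(x$M)), digits = 4),
      " trace(M2) =", format(sum(diag(x$M2)), digits = 4), "\n")
  invisible(x)
}

#' Worked 2 x 2 rotation-versus-expansion example
#'
#' The linear system \code{[[1, a], [-a, -2]]} has divergence (trace) -1
#' for every rotation weight \code{a}: its volume always contracts. Yet it
#' is linearly stable only when the rotation is fast enough: the
#' determinant is \code{a^2 - 2}, so with the negative trace the system is
#' stable iff \code{a^2 > 2}.
#'
#' @param a rotation weight.
#' @return List with \code{M}, \code{divergence} (computed trace), and
#'   \code{stable} (determinant criterion).
#' @examples
#' example_2x2(2)  # divergence -1, stable
#' example_2x2(1)  # divergence -1, unstable
#' @export
example_2x2 <- function(a) {
  M <- matrix(c(1, -a, a, -2), 2, 2)
  list(M = M, divergence = sum(diag(M)), stable = det(M) > 0)
}

#' Brute-force stability sweep of the 2 x 2 example
#'
#' Sweeps the rotation weight over a grid and records the maximal
#' eigenvalue real part of \code{[[1, a], [-a, -2]]}, locating the smallest
#' grid value at which the system becomes stable (all real parts negative).
#' Serves as the independent numerical check of the \code{a^2 > 2}
#' criterion of \code{\link{example_2x2}}.
#'
#' @param a_grid numeric grid of rotation weights.
#' @return List with \code{sweep} (data frame: a, max_re, stable) and
#'   \code{a_critical} (first stable grid value, NA if none).
#' @export
stability_sweep_2x2 <- function(a_grid = seq(0, 3, by = 0.001)) {
  max_re <- vapply(a_grid, function(a) {
    max(Re(eigen(example_2x2(a)$M, only.values = TRUE)$values))
  }, numeric(1))
  stable <- max_re < 0
  a_critical <- if (any(stable)) a_grid[which(stable)[1]] else NA_real_
  list(sweep = data.frame(a = a_grid, max_re = max_re, stable = stable),
       a_critical = a_critical)
}
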