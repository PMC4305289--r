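#' Parameter set for a soft winner-take-all motif
#'
#' Bundles the connection weights and leak conductances of the canonical
#' sWTA motif: excitatory units with self-excitation \code{alpha1}, optional
#' nearest-neighbour excitation \code{alpha2}, and a shared inhibitory unit
#' coupled by the loop weights \code{beta1} (inhibitory -> excitatory) and
#' \code{beta2} (excitatory -> inhibitory). The defaults are the reference
#' parameter set used throughout the package's worked examples
#' (alpha1 = 1.2, beta1 = 3, beta2 = 0.25, G_exc = 1.1, G_inh = 1.5),
#' which satisfies the contraction bounds (see \code{\link{validate_params}}).
#'
#' @param alpha1 self-excitation weight of each excitatory unit (> 0).
#' @param alpha2 excitation between chain neighbours (>= 0).
#' @param beta1 weight of inhibition onto excitatory units (> 0); enters the
#'   weight matrix with a negative sign.
#' @param beta2 excitatory drive onto the inhibitory unit (> 0).
#' @param g_exc leak conductance of excitatory units (> 0).
#' @param g_inh leak conductance of the inhibitory unit (> 0).
#' @param tau system time constant, in model time units (> 0).
#' @return An object of class \code{wta_params} (a named list).
#' @examples
#' p <- network_params()
#' validate_params(p)   # character(0): inside the contraction bounds
#' wta_gain(p)          # steady-state amplification for unit leaks
#' @export
network_params <- function(alpha1 = 1.2, alpha2 = 0, beta1 = 3, beta2 = 0.25,
                           g_exc = 1.1, g_inh = 1.5, tau = 1) {
  for (nm in c("alpha1", "beta1", "beta2", "g_exc", "g_inh", "tau")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(alpha2) || length(alpha2) != 1L || !is.finite(alpha2) || alpha2 < 0)
    stop("parameter 'alpha2' must be a single non-negative number", call. = FALSE)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1,
                 beta2 = beta2, g_exc = g_exc, g_inh = g_inh, tau = tau),
            class = "wta_params")
}

#' Check sWTA parameters against the contraction bounds
#'
#' A parameter set supports orderly computation (every activation subspace
#' either permitted or forbidden, bounded dynamics despite gain > 1) when
#' \code{1 < alpha1 < 2*sqrt(beta1*beta2)} and \code{1/4 < beta1*beta2 < 1}.
#' This function is diagnostic: it returns a character vector describing each
#' violated bound, empty when all bounds hold.
#'
#' @param params a \code{\link{network_params}} object.
#' @return Character vector of violated-bound descriptions (empty if valid).
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "wta_params"))
  bb <- params$beta1 * params$beta2
  out <- character(0)
  if (!(params$alpha1 > 1))
    out <- c(out, sprintf("alpha1 = %g violates 1 < alpha1", params$alpha1))
  if (!(params$alpha1 < 2 * sqrt(bb)))
    out <- c(out, sprintf("alpha1 = %g violates alpha1 < 2*sqrt(beta1*beta2) = %g",
                          params$alpha1, 2 * sqrt(bb)))
  if (!(bb > 0.25))
    out <- c(out, sprintf("beta1*beta2 = %g violates 1/4 < beta1*beta2", bb))
  if (!(bb < 1))
    out <- c(out, sprintf("beta1*beta2 = %g violates beta1*beta2 < 1", bb))
  out
}

#' Steady-state gain of the winning unit
#'
#' For unit leaks, the activation of the winner converges to \code{g * I}
#' with gain \code{g = 1 / (1 - alpha1 + beta1*beta2)}: recurrent excitation
#' amplifies the input, held in check by the inhibitory loop.
#'
#' @param params a \code{\link{network_params}} object.
#' @return The scalar gain.
#' @export
wta_gain <- function(params) {
  stopifnot(inherits(params, "wta_params"))
  den <- 1 - params$alpha1 + params$beta1 * params$beta2
  if (den <= 0)
    stop("gain denominator 1 - alpha1 + beta1*beta2 = ", den,
         " is not positive: parameters outside the stable regime", call. = FALSE)
  1 / den
}

#' Rotation-speed stability condition
#'
#' The rotational (inhibitory-loop) component of the subspace dynamics must
#' rotate fast enough to stabilise the positive self-excitation on the
#' diagonal: this holds iff \code{alpha1 < 2*sqrt(beta1*beta2)}.
#'
#' @param params a \code{\link{network_params}} object.
#' @return \code{TRUE} if the rotation is fast enough, else \code{FALSE}.
#' @export
rotation_stability <- function(params) {
  stopifnot(inherits(params, "wta_params"))
  params$alpha1 < 2 * sqrt(params$beta1 * params$beta2)
}

#' @export
print.wta_params <- function(x, ...) {
  cat("sWTA parameters: alpha1 =", x$alpha1, " alpha2 =", x$alpha2,
      " beta1 =", x$beta1, " beta2 =", x$beta2, "\n")
  cat("  leaks: G_exc =", x$g_exc, " G_inh =", x$g_inh, "  tau =", x$tau, "\n")
  v <- validate_params(x)
  if (length(v) == 0) cat("  contraction bounds: satisfied\n")
  else cat("  contraction bounds violated:\n   ", paste(v, collapse = "\n    "), "\n")
  invisible(x)
}
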