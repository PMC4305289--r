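#' Effective Jacobian of an activation subspace
#'
#' For activation pattern \code{Sigma} (diagonal 0/1), the Jacobian of the
#' rectified dynamics is \code{Sigma W - G}; units below threshold do not
#' contribute. This function returns that matrix restricted to the rows and
#' columns of the active units (an empty pattern yields a 0 x 0 matrix).
#'
#' @param net a \code{wta_network}.
#' @param pattern binary n-vector (1 = active).
#' @return The k x k effective Jacobian, k = number of active units, with
#'   unit labels as dimnames.
#' @examples
#' net <- build_wta(4)
#' effective_jacobian(net, c(1, 0, 0, 0, 1))  # one winner + inhibition
#' @export
effective_jacobian <- function(net, pattern) {
  stopifnot(inherits(net, "wta_network"), length(pattern) == net$n)
  act <- which(as.integer(pattern) == 1L)
  J <- net$W[act, act, drop = FALSE] - diag(net$G[act], nrow = length(act))
  if (length(act) > 0 && !is.null(net$labels))
    dimnames(J) <- list(net$labels[act], net$labels[act])
  J
}

#' Gaussian divergence of a linear system
#'
#' The divergence of the flow \code{dx/dt = J x} is the trace of \code{J},
#' equivalently the sum of its eigenvalues: the exponential rate at which
#' state-space volume contracts (negative) or expands (positive).
#'
#' @param J a square matrix (0 x 0 allowed; divergence 0 by convention).
#' @return The trace.
#' @export
divergence <- function(J) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J))
  if (nrow(J) == 0L) return(0)
  sum(diag(J))
}

#' Divergence of an activation subspace
#'
#' @param net a \code{wta_network}.
#' @param pattern binary n-vector.
#' @return trace of the effective Jacobian of the pattern.
#' @export
subspace_divergence <- function(net, pattern) {
  divergence(effective_jacobian(net, pattern))
}

#' Contraction metric from the eigendecomposition
#'
#' For a diagonalizable Jacobian \code{J = Q L Q^-1}, the coordinate change
#' \code{Theta = Q^-1} turns the generalized Jacobian
#' \code{Theta J Theta^-1} into \code{diag(L)}, whose Hermitian part is the
#' diagonal of eigenvalue real parts. \code{Theta^* Theta} is then a valid
#' (uniformly positive definite) contraction metric, and the system is
#' contracting in it iff all eigenvalue real parts are negative.
#'
#' @param J square matrix.
#' @return List with \code{Theta}, \code{source}
#'   (\code{"eigendecomposition"} or \code{"identity"} for a 0 x 0 or
#'   defective input), and \code{eigvals}.
#' @export
contraction_metric <- function(J) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J))
  if (nrow(J) == 0L)
    return(list(Theta = J, source = "identity", eigvals = complex(0)))
  e <- eigen(J)
  if (min(svd(e$vectors)$d) < 1e-12)
    return(list(Theta = diag(nrow(J)), source = "identity", eigvals = e$values))
  list(Theta = solve(e$vectors), source = "eigendecomposition",
       eigvals = e$values)
}

#' Classify an activation subspace as permitted or forbidden
#'
#' A subspace is \emph{permitted} (a candidate solution the dynamics never
#' leave under constant input) when its effective Jacobian is contracting in
#' the diagonalizing metric, i.e. all eigenvalue real parts are below
#' \code{-tol}. It is \emph{forbidden} when the maximal eigenvalue real part
#' exceeds \code{+tol} (expanding: neighbouring trajectories diverge) while
#' the trace is negative (state-space volume still shrinks, so the
#' expansion is transient and the subspace is escaped in finite time).
#' Patterns meeting neither test are classed \code{"neither"} and surfaced
#' rather than binned. The empty pattern is the \code{"off"} state,
#' trivially permitted (pure leak decay).
#'
#' @param net a \code{wta_network}.
#' @param pattern binary n-vector over all units.
#' @param tol eigenvalue sign tolerance.
#' @return An object of class \code{wta_subspace}: list with \code{pattern},
#'   \code{key}, \code{J_eff}, \code{eigvals}, \code{divergence},
#'   \code{klass} (\code{"permitted"|"forbidden"|"neither"|"off"}), and
#'   \code{defective} flag.
#' @export
classify_subspace <- function(net, pattern, tol = 1e-9) {
  stopifnot(inherits(net, "wta_network"), length(pattern) == net$n)
  pattern <- as.integer(pattern)
  J <- effective_jacobian(net, pattern)
  if (nrow(J) == 0L) {
    return(structure(list(pattern = pattern, key = pattern_key(pattern),
                          J_eff = J, eigvals = complex(0), divergence = 0,
                          klass = "off", defective = FALSE),
                     class = "wta_subspace"))
  }
  e <- eigen(J, only.values = FALSE)
  defective <- min(svd(e$vectors)$d) < tol
  max_re <- max(Re(e$values))
  div <- sum(diag(J))
  klass <- if (max_re < -tol) "permitted"
           else if (max_re > tol && div < 0) "forbidden"
           else "neither"
  if (defective)
    warning("effective Jacobian is defective within tolerance; ",
            "classification falls back to eigenvalue real parts", call. = FALSE)
  structure(list(pattern = pattern, key = pattern_key(pattern), J_eff = J,
                 eigvals = e$values, divergence = div, klass = klass,
                 defective = defective),
            class = "wta_subspace")
}

#' @export
print.wta_subspace <- function(x, ...) {
  cat("subspace", x$key, ":", x$klass,
      " divergence =", format(x$divergence, digits = 4),
      " max Re(eig) =",
      if (length(x$eigvals)) format(max(Re(x$eigvals)), digits = 4) else "NA",
      "\n")
  invisible(x)
}

# Derive the full pattern from an excitatory-only pattern: an inhibitory
# unit is active whenever at least one excitatory unit driving it is active.
full_pattern_from_exc <- function(net, exc_pattern) {
  exc <- exc_indices(net)
  stopifnot(length(exc_pattern) == length(exc))
  pattern <- integer(net$n)
  pattern[exc] <- as.integer(exc_pattern)
  for (j in inh_indices(net)) {
    drivers <- exc[net$W[j, exc] != 0]
    pattern[j] <- as.integer(any(pattern[drivers] == 1L))
  }
  pattern
}

#' Enumerate and classify all activation subspaces
#'
#' Enumerates the 2^k binary patterns over the excitatory units (inhibitory
#' units are marked active whenever a connected excitatory unit is active),
#' classifies each with \code{\link{classify_subspace}}, and assigns
#' enumeration indices ordered by divergence descending -- with the off
#' state placed last, and ties broken by the pattern read as an integer --
#' so that the single-winner (most contracting) subspaces come just before
#' the off state. With \code{mode = "full"} the patterns range over all
#' units, which is the appropriate accounting for grid networks with many
#' inhibitory units.
#'
#' @param net a \code{wta_network}.
#' @param mode \code{"excitatory"} (default) or \code{"full"}.
#' @param cap refuse enumeration when the number of pattern bits exceeds
#'   this (2^k growth); sample patterns instead for larger networks.
#' @param tol eigenvalue tolerance passed to \code{classify_subspace}.
#' @return A data frame of class \code{wta_subspace_table} with columns
#'   \code{index}, \code{key} (bitstring over all units), \code{exc_key}
#'   (over excitatory units), \code{n_active_exc}, \code{divergence},
#'   \code{max_re}, \code{klass}; the \code{wta_subspace} objects are
#'   attached as the \code{"subspaces"} attribute (in index order).
#' @examples
#' tab <- enumerate_subspaces(build_wta(4))
#' table(tab$klass)   # 4 single-winner permitted, 11 forbidden, 1 off
#' @export
enumerate_subspaces <- function(net, mode = c("excitatory", "full"),
                                cap = 20, tol = 1e-9) {
  stopifnot(inherits(net, "wta_network"))
  mode <- match.arg(mode)
  bits <- if (mode == "excitatory") length(exc_indices(net)) else net$n
  if (bits > cap)
    stop("enumeration over ", bits, " units exceeds cap = ", cap,
         " (2^k patterns); sample patterns and use classify_subspace() instead",
         call. = FALSE)
  n_pat <- 2L^bits
  subs <- vector("list", n_pat)
  for (m in seq_len(n_pat) - 1L) {
    bp <- as.integer(intToBits(m)[seq_len(bits)])  # bit 1 = unit 1
    pattern <- if (mode == "excitatory") full_pattern_from_exc(net, bp)
               else bp
    subs[[m + 1L]] <- classify_subspace(net, pattern, tol = tol)
  }
  div <- vapply(subs, function(s) s$divergence, numeric(1))
  is_off <- vapply(subs, function(s) s$klass == "off", logical(1))
  pat_int <- seq_len(n_pat) - 1L
  ord <- order(is_off, -div, pat_int)
  subs <- subs[ord]
  tab <- data.frame(
    index = seq_len(n_pat),
    key = vapply(subs, function(s) s$key, character(1)),
    exc_key = vapply(subs, function(s)
      pattern_key(s$pattern[exc_indices(net)]), character(1)),
    n_active_exc = vapply(subs, function(s)
      sum(s$pattern[exc_indices(net)]), numeric(1)),
    divergence = vapply(subs, function(s) s$divergence, numeric(1)),
    max_re = vapply(subs, function(s)
      if (length(s$eigvals)) max(Re(s$eigvals)) else NA_real_, numeric(1)),
    klass = vapply(subs, function(s) s$klass, character(1)),
    stringsAsFactors = FALSE)
  attr(tab, "subspaces") <- subs
  attr(tab, "mode") <- mode
  class(tab) <- c("wta_subspace_table", "data.frame")
  tab
}

#' Expansion test via the instability projection matrix V
#'
#' Builds the projection \code{V} with one row per active excitatory unit
#' \code{i}: entry \code{alpha1} in column \code{i} and \code{-beta1} in the
#' column of its inhibitory unit (the two-unit case generalised row-wise;
#' columns restricted to the active units). \code{V x} collects each active
#' unit's recurrent drive margin; the subspace cannot hold \code{V x}
#' steady -- it is expanding -- iff \code{V J V^T} has an eigenvalue with
#' positive real part, i.e. the Hermitian part of the generalized Jacobian
#' in the diagonalizing metric has a positive entry.
#'
#' @param net a \code{wta_network}.
#' @param pattern binary n-vector with at least one active excitatory unit.
#' @param tol eigenvalue tolerance.
#' @return List with \code{expanding} (logical), \code{V} (rows named by
#'   unit), \code{VJVt}, and \code{max_re}.
#' @export
expansion_test <- function(net, pattern, tol = 1e-9) {
  stopifnot(inherits(net, "wta_network"), length(pattern) == net$n)
  pattern <- as.integer(pattern)
  act <- which(pattern == 1L)
  act_exc <- act[net$types[act] == "exc"]
  if (length(act_exc) == 0L)
    stop("pattern has no active excitatory unit", call. = FALSE)
  p <- net$params
  if (is.null(p)) stop("network carries no parameter set", call. = FALSE)
  V_full <- matrix(0, length(act_exc), net$n)
  for (r in seq_along(act_exc)) {
    i <- act_exc[r]
    V_full[r, i] <- p$alpha1
    inh_of_i <- which(net$types == "inh" & net$W[i, ] < 0)
    V_full[r, inh_of_i] <- -p$beta1
  }
  V <- V_full[, act, drop = FALSE]
  J <- effective_jacobian(net, pattern)
  A <- V %*% J %*% t(V)
  max_re <- max(Re(eigen(A, only.values = TRUE)$values))
  list(expanding = max_re > tol, V = V, VJVt = A, max_re = max_re)
}

#' Mixed-eigenvector check for a forbidden subspace
#'
#' The eigenvector of the maximal-real-part eigenvalue of a forbidden
#' subspace's effective Jacobian must be mixed -- contain at least one
#' strictly positive and one strictly negative component -- which
#' guarantees that some unit is driven below threshold so the active set
#' changes. The global sign of the eigenvector is normalised by its
#' largest-magnitude component; entries within \code{tol} (relative) of
#' zero are ignored. A complex top eigenvalue is evaluated on the real part
#' of its eigenvector and flagged.
#'
#' @param J effective Jacobian with \code{max Re(eig) > 0}.
#' @param tol relative tolerance for near-zero components.
#' @return Logical; attribute \code{"complex_top"} marks the flagged case.
#' @export
mixed_eigenvector_check <- function(J, tol = 1e-9) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J), nrow(J) >= 1)
  e <- eigen(J)
  top <- which.max(Re(e$values))
  if (Re(e$values[top]) <= 0)
    stop("maximal eigenvalue real part is not positive", call. = FALSE)
  complex_top <- abs(Im(e$values[top])) > tol
  v <- e$vectors[, top]
  v <- Re(v * Conj(v[which.max(Mod(v))]) / Mod(v[which.max(Mod(v))]))
  thr <- tol * max(abs(v))
  res <- any(v > thr) && any(v < -thr)
  attr(res, "complex_top") <- complex_top
  res
}

#' Closed-form steady state of a winning unit
#'
#' With the winner \code{w} and its inhibitory unit the only active units
#' under constant input \code{I} to the winner, the fixed point of the
#' linear regime is \code{x_w = I / (G_w - alpha1 + beta1*beta2 / G_inh)},
#' the leak-generalised form of the gain relation (for unit leaks it
#' reduces to \code{wta_gain(params) * I}). Used as the analytic oracle for
#' converged simulations.
#'
#' @param net a \code{wta_network} built by \code{\link{build_wta}}.
#' @param winner index of the winning excitatory unit.
#' @param I constant external input to the winner.
#' @return The winner's steady-state activation.
#' @export
steady_state_winner <- function(net, winner, I) {
  stopifnot(inherits(net, "wta_network"), net$types[winner] == "exc")
  inh <- which(net$types == "inh" & net$W[winner, ] < 0)
  if (length(inh) != 1L)
    stop("winner must participate in exactly one inhibitory loop", call. = FALSE)
  alpha1 <- net$W[winner, winner]
  beta1 <- -net$W[winner, inh]
  beta2 <- net$W[inh, winner]
  den <- net$G[winner] - alpha1 + beta1 * beta2 / net$G[inh]
  if (den <= 0)
    stop("steady-state denominator ", den,
         " not positive: parameters outside the stable regime", call. = FALSE)
  I / den
}
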