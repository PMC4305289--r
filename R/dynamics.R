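#' Input protocol for a simulation run
#'
#' External inputs are zero until \code{onset_step} and constant afterwards.
#' The constant values can be given explicitly (\code{base_input}, one value
#' per unit; inhibitory entries must be 0) or drawn at simulation time
#' i.i.d. from N(\code{input_mu}, \code{input_sigma}) for the excitatory
#' units. Optional additive noise N(0, \code{noise_sigma}) is applied to the
#' excitatory inputs from onset onward and redrawn every
#' \code{noise_resample_period} steps (one time constant, by default, to
#' avoid integration artefacts). State-conditional rules add an input
#' increment to a target unit while the network occupies a trigger
#' activation pattern, which steers transitions against the divergence
#' gradient.
#'
#' @param onset_step integration step at which inputs switch on (>= 0).
#' @param base_input optional explicit n-vector of constant inputs.
#' @param input_mu,input_sigma mean and sd of the per-run input draw used
#'   when \code{base_input} is \code{NULL}. \code{input_sigma} is a standard
#'   deviation.
#' @param noise_sigma sd of the additive input noise (0 = none).
#' @param noise_resample_period steps between noise redraws (>= 1).
#' @param conditional_rules list of rules, each a list with elements
#'   \code{trigger} (binary n-pattern), \code{target} (unit index) and
#'   \code{increment} (input increase while the trigger pattern is active).
#' @return An object of class \code{wta_protocol}.
#' @export
input_protocol <- function(onset_step = 2000, base_input = NULL,
                           input_mu = 6, input_sigma = 1,
                           noise_sigma = 0, noise_resample_period = 100,
                           conditional_rules = list()) {
  stopifnot(onset_step >= 0, noise_sigma >= 0, noise_resample_period >= 1,
            input_sigma >= 0)
  for (r in conditional_rules)
    stopifnot(is.list(r), all(c("trigger", "target", "increment") %in% names(r)))
  structure(list(onset_step = as.integer(onset_step), base_input = base_input,
                 input_mu = input_mu, input_sigma = input_sigma,
                 noise_sigma = noise_sigma,
                 noise_resample_period = as.integer(noise_resample_period),
                 conditional_rules = conditional_rules),
            class = "wta_protocol")
}

#' One Euler step of the rectified dynamics
#'
#' Advances the state by \code{x + (dt/tau) * (f(W x + drive) - G * x)} with
#' \code{f(u) = max(u, 0)}. Exposed mainly for inspection and testing; full
#' runs go through \code{\link{simulate_network}}.
#'
#' @param net a \code{wta_network}.
#' @param x state n-vector (finite).
#' @param drive input n-vector.
#' @param dt Euler step size (> 0).
#' @return The updated state vector.
#' @export
step_state <- function(net, x, drive, dt = 0.01) {
  stopifnot(inherits(net, "wta_network"), dt > 0,
            length(x) == net$n, length(drive) == net$n, all(is.finite(x)))
  u <- as.numeric(net$W %*% x) + drive
  x_new <- x + dt / net$tau * (pmax(u, 0) - net$G * x)
  if (any(!is.finite(x_new)))
    stop("non-finite state for unit(s) ",
         paste(which(!is.finite(x_new)), collapse = ", "),
         ": parameters outside the bounded regime", call. = FALSE)
  x_new
}

#' Activation pattern of a state
#'
#' A unit is active iff its rectifier argument \code{(W x + drive)_i > 0} --
#' the same quantity whose sign gates the switching matrix in the effective
#' Jacobian. With \code{use_state = TRUE} the alternative state-based rule
#' \code{x_i > eps} is used instead.
#'
#' @param net a \code{wta_network}.
#' @param x state n-vector.
#' @param drive input n-vector.
#' @param use_state use \code{x > eps} instead of the rectifier argument.
#' @param eps threshold for the state-based rule.
#' @return Integer 0/1 vector of length n.
#' @export
active_pattern <- function(net, x, drive = numeric(net$n),
                           use_state = FALSE, eps = 1e-9) {
  stopifnot(inherits(net, "wta_network"),
            length(x) == net$n, length(drive) == net$n)
  if (use_state) return(as.integer(x > eps))
  as.integer(as.numeric(net$W %*% x) + drive > 0)
}

#' Simulate a network under an input protocol
#'
#' Integrates the rectified dynamics with the Euler scheme
#' (\code{dt = 0.01} by default, so one time constant \code{tau = 1} spans
#' 100 steps), applying the protocol's inputs, noise, and conditional rules,
#' and recording state, realised input, and activation pattern along with
#' every pattern transition. Deterministic given \code{seed}.
#'
#' @param net a \code{wta_network}.
#' @param protocol a \code{\link{input_protocol}}.
#' @param n_steps number of Euler steps (>= 1).
#' @param x0 initial state: a non-negative n-vector, or \code{"zero"}
#'   (default) or \code{"uniform"} (i.i.d. U[0,1), seeded).
#' @param seed RNG seed (used for input draws, initial state, noise).
#' @param dt Euler step size.
#' @param record_stride record state/pattern every this many steps
#'   (1 = every step; transitions are always logged at full resolution).
#' @param record_state record X and I matrices (disable to save memory in
#'   large ensembles).
#' @return An object of class \code{wta_trajectory}: list with \code{steps},
#'   \code{X}, \code{I}, \code{active} (rows = recorded steps),
#'   \code{transitions} (data frame: step, from, to bitstrings over all
#'   units), \code{x_final}, \code{base_input}, \code{seed}.
#' @examples
#' net <- build_wta(4)
#' tr <- simulate_network(net, input_protocol(input_sigma = 1),
#'                        n_steps = 6000, seed = 1)
#' tail(tr$transitions, 3)  # descent through forbidden subspaces
#' @export
simulate_network <- function(net, protocol = input_protocol(), n_steps = 10000,
                             x0 = "zero", seed = NULL, dt = 0.01,
                             record_stride = 1, record_state = TRUE) {
  stopifnot(inherits(net, "wta_network"), inherits(protocol, "wta_protocol"),
            n_steps >= 1, dt > 0, record_stride >= 1)
  if (net$n == 0L) stop("empty network", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  is_exc <- net$types == "exc"
  if (is.character(x0)) {
    x0 <- switch(match.arg(x0, c("zero", "uniform")),
                 zero = numeric(net$n),
                 uniform = stats::runif(net$n))
  }
  stopifnot(length(x0) == net$n, all(x0 >= 0))
  base <- protocol$base_input
  if (is.null(base)) {
    base <- numeric(net$n)
    base[is_exc] <- stats::rnorm(sum(is_exc), protocol$input_mu,
                                 protocol$input_sigma)
  }
  stopifnot(length(base) == net$n)
  if (any(base[!is_exc] != 0))
    stop("inhibitory units receive no external drive", call. = FALSE)

  rules <- protocol$conditional_rules
  n_rules <- length(rules)
  trig <- matrix(0L, n_rules, net$n)
  targ <- integer(n_rules); incr <- numeric(n_rules)
  for (r in seq_len(n_rules)) {
    stopifnot(length(rules[[r]]$trigger) == net$n)
    trig[r, ] <- as.integer(rules[[r]]$trigger)
    targ[r] <- as.integer(rules[[r]]$target) - 1L
    incr[r] <- rules[[r]]$increment
  }

  res <- sim_core(net$W, net$G, net$tau, is_exc, x0, base,
                  as.integer(n_steps), protocol$onset_step,
                  protocol$noise_sigma, protocol$noise_resample_period, dt,
                  trig, targ, incr, as.integer(record_stride), record_state)
  transitions <- data.frame(
    step = res$trans_step,
    from = pattern_keys(res$trans_from),
    to = pattern_keys(res$trans_to),
    stringsAsFactors = FALSE)
  structure(list(steps = res$steps,
                 X = if (record_state) res$X else NULL,
                 I = if (record_state) res$I else NULL,
                 active = res$patterns,
                 transitions = transitions,
                 x_final = res$x_final,
                 base_input = base, seed = seed, dt = dt,
                 record_stride = record_stride, net = net,
                 protocol = protocol),
            class = "wta_trajectory")
}

#' @export
print.wta_trajectory <- function(x, ...) {
  cat("wta_trajectory:", max(x$steps), "steps,", nrow(x$transitions),
      "pattern transitions\n")
  cat("  final pattern:", pattern_key(x$active[nrow(x$active), ]), "\n")
  invisible(x)
}

# bitstring keys for binary patterns ("0110..."), rows of a matrix
pattern_key <- function(p) paste(as.integer(p), collapse = "")
pattern_keys <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  apply(m, 1L, pattern_key)
}
key_to_pattern <- function(key) as.integer(strsplit(key, "")[[1]])
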