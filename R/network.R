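#' Construct a chain soft winner-take-all network
#'
#' Builds a network of \code{n_exc} excitatory linear threshold units
#' competing through one shared inhibitory unit (placed last, index
#' \code{n_exc + 1}). Each excitatory unit excites itself with
#' \code{alpha1}, its chain neighbours \code{i - 1} and \code{i + 1} with
#' \code{alpha2} (finite chain, no wraparound), and is inhibited with
#' \code{-beta1} by the inhibitory unit, which in turn sums \code{beta2}
#' from every excitatory unit. The weight convention is
#' \code{W[i, j]} = weight of the connection from presynaptic \code{j} to
#' postsynaptic \code{i}, so the dynamics read
#' \code{tau * dx/dt = f(W x + I) - G x} with \code{f(u) = max(u, 0)}.
#'
#' @param n_exc number of excitatory units (>= 1).
#' @param params a \code{\link{network_params}} object.
#' @param strict if \code{TRUE}, error when the parameters violate the
#'   contraction bounds (see \code{\link{validate_params}}); if \code{FALSE}
#'   (default) only warn.
#' @return An object of class \code{wta_network}: a list with elements
#'   \code{n}, \code{types} (\code{"exc"}/\code{"inh"} per unit), \code{W},
#'   \code{G}, \code{tau}, \code{labels}, \code{params}.
#' @examples
#' net <- build_wta(4)           # the 5-unit reference network
#' net$W[1:2, 5]                 # -beta1 inhibition onto units 1 and 2
#' @export
build_wta <- function(n_exc, params = network_params(), strict = FALSE) {
  stopifnot(inherits(params, "wta_params"))
  if (!is.numeric(n_exc) || length(n_exc) != 1L || n_exc < 1 || n_exc != round(n_exc))
    stop("n_exc must be a positive integer", call. = FALSE)
  viol <- validate_params(params)
  if (length(viol) > 0) {
    msg <- paste0("parameters violate contraction bounds: ",
                  paste(viol, collapse = "; "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  n_exc <- as.integer(n_exc)
  n <- n_exc + 1L
  W <- matrix(0, n, n)
  for (i in seq_len(n_exc)) {
    W[i, i] <- params$alpha1
    if (i > 1L) W[i, i - 1L] <- params$alpha2
    if (i < n_exc) W[i, i + 1L] <- params$alpha2
    W[i, n] <- -params$beta1
    W[n, i] <- params$beta2
  }
  types <- c(rep("exc", n_exc), "inh")
  labels <- c(paste0("x", seq_len(n_exc)), "inh")
  new_wta_network(n, types, W,
                  G = c(rep(params$g_exc, n_exc), params$g_inh),
                  tau = params$tau, labels = labels, params = params)
}

new_wta_network <- function(n, types, W, G, tau, labels = NULL, params = NULL,
                            coords = NULL, unbounded = FALSE) {
  net <- structure(list(n = as.integer(n), types = types, W = W, G = G,
                        tau = tau, labels = labels, params = params,
                        coords = coords, unbounded = unbounded),
                   class = "wta_network")
  check_network(net)
  net
}

# Dale-sign and shape invariants; called by every builder and reader.
check_network <- function(net) {
  n <- net$n
  if (n == 0L) return(invisible(net))
  stopifnot(is.matrix(net$W), nrow(net$W) == n, ncol(net$W) == n,
            length(net$G) == n, length(net$types) == n)
  if (any(net$G <= 0)) stop("leaks G must be strictly positive", call. = FALSE)
  if (!all(net$types %in% c("exc", "inh")))
    stop("unit types must be 'exc' or 'inh'", call. = FALSE)
  for (j in seq_len(n)) {
    col <- net$W[, j]
    if (net$types[j] == "exc" && any(col < 0))
      stop("column ", j, " is excitatory but has negative entries", call. = FALSE)
    if (net$types[j] == "inh" && any(col > 0))
      stop("column ", j, " is inhibitory but has positive entries", call. = FALSE)
    if (net$types[j] == "inh" && net$W[j, j] != 0)
      stop("inhibitory unit ", j, " has a nonzero self-connection", call. = FALSE)
  }
  invisible(net)
}

#' Add or overwrite a single connection
#'
#' Sets \code{W[dst, src]} to \code{w}. The sign of \code{w} must be
#' consistent with the type of the presynaptic unit \code{src}
#' (\code{w >= 0} for excitatory, \code{w <= 0} for inhibitory). Used, for
#' instance, to steer the competition by adding weak excitatory
#' cross-connections between chain units.
#'
#' @param net a \code{wta_network}.
#' @param src presynaptic unit index.
#' @param dst postsynaptic unit index.
#' @param w connection weight.
#' @return The modified network.
#' @examples
#' net <- build_wta(4)
#' net <- add_connection(net, src = 1, dst = 2, w = 0.2)
#' net <- add_connection(net, src = 4, dst = 2, w = 0.2)
#' @export
add_connection <- function(net, src, dst, w) {
  stopifnot(inherits(net, "wta_network"))
  if (src < 1 || src > net$n || dst < 1 || dst > net$n)
    stop("unit index out of range", call. = FALSE)
  if (net$types[src] == "exc" && w < 0)
    stop("source unit ", src, " is excitatory: weight must be >= 0", call. = FALSE)
  if (net$types[src] == "inh" && w > 0)
    stop("source unit ", src, " is inhibitory: weight must be <= 0", call. = FALSE)
  net$W[dst, src] <- w
  check_network(net)
  net
}

#' Specification of a random grid network
#'
#' Describes the probabilistic assembly of a network from sWTA motifs placed
#' on a square grid: each spot holds a neuron with probability
#' \code{p_occupied}; an occupied spot is excitatory with probability
#' \code{p_exc}, otherwise inhibitory. Every excitatory unit excites itself
#' with \code{alpha1} and is wired into up to \code{max_inh_partners}
#' reciprocal loops with randomly chosen inhibitory units, each candidate
#' kept with probability \code{p_connect} (so the chance of an isolated
#' excitatory unit is \code{(1 - p_connect)^max_inh_partners}).
#'
#' @param side grid side length (>= 1).
#' @param p_occupied probability a spot is occupied.
#' @param p_exc probability an occupied spot is excitatory.
#' @param max_inh_partners candidate inhibitory partners per excitatory unit.
#' @param p_connect per-candidate connection probability.
#' @param params a \code{\link{network_params}} object supplying
#'   alpha1/beta1/beta2 and the leaks.
#' @param normalize_inhibition divide the inhibitory weight received by
#'   each excitatory unit by its number of realized loops, so the unit's
#'   aggregate loop gain stays at \code{beta1*beta2} -- inside the
#'   per-neuron contraction bounds -- however many partners it drew
#'   (default \code{TRUE}; \code{FALSE} gives each loop the full
#'   \code{-beta1}).
#' @param seed RNG seed making the assembly reproducible.
#' @return An object of class \code{wta_grid_spec}.
#' @export
grid_spec <- function(side = 10, p_occupied = 0.4, p_exc = 0.8,
                      max_inh_partners = 8, p_connect = 0.4,
                      params = network_params(),
                      normalize_inhibition = TRUE, seed = 1L) {
  stopifnot(side >= 1, side == round(side),
            p_occupied >= 0, p_occupied <= 1,
            p_exc >= 0, p_exc <= 1,
            p_connect >= 0, p_connect <= 1,
            max_inh_partners >= 0, max_inh_partners == round(max_inh_partners),
            inherits(params, "wta_params"))
  structure(list(side = as.integer(side), p_occupied = p_occupied,
                 p_exc = p_exc, max_inh_partners = as.integer(max_inh_partners),
                 p_connect = p_connect, params = params,
                 normalize_inhibition = isTRUE(normalize_inhibition),
                 seed = as.integer(seed)),
            class = "wta_grid_spec")
}

#' Assemble a random grid network
#'
#' Realises a \code{\link{grid_spec}}: occupies grid spots, assigns types,
#' gives every excitatory unit a self-excitation \code{alpha1}, and samples
#' for each excitatory unit up to \code{max_inh_partners} distinct
#' inhibitory candidates (uniformly without replacement), keeping each with
#' probability \code{p_connect}; a kept pair becomes a reciprocal loop
#' (excitatory -> inhibitory weight \code{beta2}, inhibitory -> excitatory
#' weight \code{-beta1}, divided by the unit's number of realized loops
#' when \code{normalize_inhibition} is set -- see \code{\link{grid_spec}}).
#' Deterministic given \code{spec$seed}.
#'
#' If the realised grid contains excitatory units but no inhibitory unit,
#' the network is flagged \code{unbounded = TRUE} (nothing limits activity
#' growth) and a warning is raised.
#'
#' @param spec a \code{wta_grid_spec}.
#' @return A \code{wta_network}; \code{coords} holds the (row, col) grid
#'   position of each unit.
#' @export
build_random_grid <- function(spec) {
  stopifnot(inherits(spec, "wta_grid_spec"))
  p <- spec$params
  set.seed(spec$seed)
  n_spots <- spec$side^2
  occupied <- stats::runif(n_spots) < spec$p_occupied
  idx <- which(occupied)
  n <- length(idx)
  if (n == 0L) {
    return(structure(list(n = 0L, types = character(0),
                          W = matrix(0, 0, 0), G = numeric(0),
                          tau = p$tau, labels = character(0), params = p,
                          coords = matrix(0, 0, 2), unbounded = FALSE),
                     class = "wta_network"))
  }
  types <- ifelse(stats::runif(n) < spec$p_exc, "exc", "inh")
  W <- matrix(0, n, n)
  exc <- which(types == "exc")
  inh <- which(types == "inh")
  for (i in exc) W[i, i] <- p$alpha1
  if (length(inh) > 0) {
    for (i in exc) {
      k <- min(spec$max_inh_partners, length(inh))
      if (k == 0L) next
      cand <- if (length(inh) == 1L) inh else sample(inh, k)
      keep <- cand[stats::runif(k) < spec$p_connect]
      b1 <- if (spec$normalize_inhibition && length(keep) > 0)
        p$beta1 / length(keep) else p$beta1
      for (j in keep) {
        W[j, i] <- p$beta2  # excitatory -> inhibitory
        W[i, j] <- -b1      # inhibitory -> excitatory
      }
    }
  }
  unbounded <- length(inh) == 0L && length(exc) > 0L
  if (unbounded)
    warning("grid contains no inhibitory units: activity is not guaranteed bounded",
            call. = FALSE)
  coords <- cbind(row = (idx - 1L) %/% spec$side + 1L,
                  col = (idx - 1L) %% spec$side + 1L)
  G <- ifelse(types == "exc", p$g_exc, p$g_inh)
  labels <- paste0(ifelse(types == "exc", "e", "i"), seq_len(n))
  new_wta_network(n, types, W, G, tau = p$tau, labels = labels, params = p,
                  coords = coords, unbounded = unbounded)
}

#' @export
print.wta_network <- function(x, ...) {
  cat("wta_network:", x$n, "units (", sum(x$types == "exc"), "excitatory,",
      sum(x$types == "inh"), "inhibitory ), tau =", x$tau, "\n")
  if (isTRUE(x$unbounded))
    cat("  WARNING: no inhibitory units; dynamics not guaranteed bounded\n")
  invisible(x)
}

n_exc_units <- function(net) sum(net$types == "exc")
exc_indices <- function(net) which(net$types == "exc")
inh_indices <- function(net) which(net$types == "inh")
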