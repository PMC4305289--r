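#' Run an ensemble of simulations
#'
#' Repeats \code{\link{simulate_network}} over \code{n_runs} independent
#' runs (fresh input draws, initial conditions, and noise per run),
#' pooling: the per-recorded-step occupancy distribution over activation
#' subspaces, its Shannon entropy curve H(t), the pooled post-onset
#' transition log with source/destination divergences, the transition
#' graph, the against-gradient transition fraction, and each run's first
#' entry into a permitted subspace.
#'
#' Per-run child seeds are drawn once from the master \code{seed}
#' (\code{sample.int} after \code{set.seed(seed)}), so any single run can
#' be reproduced in isolation from its recorded child seed.
#'
#' @param net a \code{wta_network}.
#' @param protocol an \code{\link{input_protocol}} template; inputs are
#'   redrawn per run unless \code{base_input} is fixed.
#' @param n_runs number of runs (>= 1).
#' @param seed master RNG seed.
#' @param n_steps Euler steps per run.
#' @param x0 initial-state rule per run (default \code{"uniform"}).
#' @param dt Euler step size.
#' @param record_stride occupancy recording stride in steps (default 100,
#'   one time constant).
#' @param mode subspace identity: \code{"excitatory"} (patterns over
#'   excitatory units; default) or \code{"full"} (all units; use for grids
#'   with several inhibitory units).
#' @param budget_steps censoring budget for \code{time_to_permitted},
#'   in steps after onset (default: all remaining steps).
#' @return An object of class \code{wta_ensemble}: list with \code{n_runs},
#'   \code{run_seeds}, \code{occupancy} (data frame step/pattern/p),
#'   \code{entropy} (step/H/n_patterns), \code{transitions} (pooled
#'   post-onset: run/step/from/to/div_from/div_to/in_computation, the last
#'   marking transitions up to the run's first permitted entry),
#'   \code{graph} (see \code{\link{transition_graph}}),
#'   \code{against_gradient_fraction} (computation window; NA when no
#'   transitions), \code{time_to_permitted} (per run, steps
#'   after onset; NA when censored), \code{censored} (logical per run).
#' @examples
#' net <- build_wta(4)
#' ens <- run_ensemble(net, input_protocol(input_sigma = 0.25),
#'                     n_runs = 50, seed = 1, n_steps = 8000)
#' head(ens$entropy)
#' @export
run_ensemble <- function(net, protocol = input_protocol(), n_runs = 1000,
                         seed = 1, n_steps = 10000, x0 = "uniform",
                         dt = 0.01, record_stride = 100,
                         mode = c("excitatory", "full"),
                         budget_steps = NULL) {
  stopifnot(inherits(net, "wta_network"), n_runs >= 1)
  mode <- match.arg(mode)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  onset <- protocol$onset_step
  if (is.null(budget_steps)) budget_steps <- n_steps - onset

  exc <- exc_indices(net)
  cache <- new.env(parent = emptyenv())
  info_of <- function(key) {
    if (is.null(cache[[key]])) {
      s <- classify_subspace(net, key_to_pattern(key))
      cache[[key]] <- list(div = s$divergence, klass = s$klass)
    }
    cache[[key]]
  }
  mode_key <- function(key) {
    if (mode == "full") key else
      pattern_key(key_to_pattern(key)[exc])
  }

  occ_keys <- NULL
  trans_list <- vector("list", n_runs)
  ttp <- rep(NA_real_, n_runs)
  censored <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    tr <- simulate_network(net, protocol, n_steps = n_steps, x0 = x0,
                           seed = run_seeds[r], dt = dt,
                           record_stride = record_stride,
                           record_state = FALSE)
    keys_full <- pattern_keys(tr$active)
    if (is.null(occ_keys))
      occ_keys <- matrix(NA_character_, n_runs, length(keys_full))
    occ_keys[r, ] <- vapply(keys_full, mode_key, character(1), USE.NAMES = FALSE)

    trs <- tr$transitions
    # first permitted subspace entered at or after onset
    ev_steps <- c(0L, trs$step)
    ev_keys <- c(pattern_key(tr$active[1, ]), trs$to)
    at_onset <- max(which(ev_steps <= onset))
    first_perm <- NA_real_
    first_perm_abs <- Inf
    for (k in at_onset:length(ev_steps)) {
      if (info_of(ev_keys[k])$klass %in% c("permitted", "off")) {
        first_perm_abs <- ev_steps[k]
        first_perm <- max(ev_steps[k], onset) - onset
        break
      }
    }
    if (is.na(first_perm) || first_perm > budget_steps) {
      censored[r] <- TRUE
    } else {
      ttp[r] <- first_perm
    }
    post <- trs[trs$step > onset, , drop = FALSE]
    if (nrow(post) > 0) {
      post$run <- r
      post$in_computation <- post$step <= first_perm_abs
      trans_list[[r]] <- post
    }
  }

  steps_rec <- seq(0L, n_steps, by = record_stride)
  occupancy <- do.call(rbind, lapply(seq_along(steps_rec), function(j) {
    tabcnt <- table(occ_keys[, j])
    data.frame(step = steps_rec[j], pattern = names(tabcnt),
               p = as.numeric(tabcnt) / n_runs, stringsAsFactors = FALSE)
  }))
  rownames(occupancy) <- NULL

  transitions <- do.call(rbind, trans_list)
  if (is.null(transitions))
    transitions <- data.frame(run = integer(0), step = integer(0),
                              from = character(0), to = character(0),
                              in_computation = logical(0),
                              stringsAsFactors = FALSE)
  if (nrow(transitions) > 0) {
    transitions$div_from <- vapply(transitions$from,
                                   function(k) info_of(k)$div, numeric(1),
                                   USE.NAMES = FALSE)
    transitions$div_to <- vapply(transitions$to,
                                 function(k) info_of(k)$div, numeric(1),
                                 USE.NAMES = FALSE)
    transitions <- transitions[, c("run", "step", "from", "to",
                                   "div_from", "div_to", "in_computation")]
  } else {
    transitions$div_from <- numeric(0)
    transitions$div_to <- numeric(0)
  }

  comp <- transitions[transitions$in_computation, , drop = FALSE]
  agf <- if (nrow(comp) > 0)
    mean(comp$div_to > comp$div_from) else NA_real_

  res <- structure(list(n_runs = n_runs, run_seeds = run_seeds,
                        onset_step = onset, record_stride = record_stride,
                        mode = mode, occupancy = occupancy,
                        entropy = entropy_curve(occupancy),
                        transitions = transitions,
                        against_gradient_fraction = agf,
                        time_to_permitted = ttp, censored = censored,
                        net = net, protocol = protocol),
                   class = "wta_ensemble")
  res$graph <- transition_graph(res)
  res
}

#' @export
print.wta_ensemble <- function(x, ...) {
  cat("wta_ensemble:", x$n_runs, "runs,", nrow(x$transitions),
      "pooled post-onset transitions\n")
  H <- x$entropy
  cat("  entropy: peak", format(max(H$H), digits = 3), "bits at step",
      H$step[which.max(H$H)], "; final",
      format(H$H[nrow(H)], digits = 3), "bits\n")
  if (!is.na(x$against_gradient_fraction))
    cat("  against-gradient fraction:",
        format(x$against_gradient_fraction, digits = 3), "\n")
  invisible(x)
}

#' Shannon entropy of the occupancy distribution over time
#'
#' Computes \code{H(t) = -sum_i p_i(t) log2 p_i(t)} (bits) per recorded
#' step, with the convention \code{0 * log2(0) = 0}.
#'
#' @param occupancy data frame with columns \code{step}, \code{pattern},
#'   \code{p} (probabilities summing to 1 within each step).
#' @return Data frame with columns \code{step}, \code{H},
#'   \code{n_patterns}.
#' @export
entropy_curve <- function(occupancy) {
  stopifnot(all(c("step", "pattern", "p") %in% names(occupancy)))
  out <- lapply(split(occupancy, occupancy$step), function(d) {
    p <- d$p[d$p > 0]
    data.frame(step = d$step[1], H = -sum(p * log2(p)) + 0,  # avoid -0
               n_patterns = length(p))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$step), ]
  rownames(out) <- NULL
  out
}

#' Fraction of transitions against the divergence gradient
#'
#' Under constant input without noise every subspace transition strictly
#' decreases the divergence; changing inputs (noise, conditional rules) can
#' push the network to a subspace with larger divergence. This returns the
#' fraction of pooled post-onset transitions whose destination divergence
#' exceeds the source divergence.
#'
#' The default window, \code{"computation"}, counts each run's transitions
#' from input onset up to and including its first entry into a permitted
#' subspace -- the transitions of the computation proper. This makes the
#' fraction independent of the simulation budget: after convergence, input
#' noise keeps producing paired up/down excursions at a constant rate, so
#' pooling over the whole run (\code{window = "all"}) yields a number that
#' grows with run length towards 1/2 rather than a property of the network.
#'
#' @param x a \code{wta_ensemble}, or a transitions data frame with columns
#'   \code{div_from}, \code{div_to} (and \code{in_computation} for the
#'   default window).
#' @param window \code{"computation"} (default) or \code{"all"}.
#' @return Scalar fraction in [0, 1].
#' @export
against_gradient_fraction <- function(x, window = c("computation", "all")) {
  window <- match.arg(window)
  tr <- if (inherits(x, "wta_ensemble")) x$transitions else x
  stopifnot(all(c("div_from", "div_to") %in% names(tr)))
  if (window == "computation") {
    stopifnot("in_computation" %in% names(tr))
    tr <- tr[tr$in_computation, , drop = FALSE]
  }
  if (nrow(tr) == 0)
    stop("no transitions recorded: fraction undefined", call. = FALSE)
  mean(tr$div_to > tr$div_from)
}

#' Transition graph of an ensemble
#'
#' Builds the directed multigraph of subspace-to-subspace transitions
#' pooled over the ensemble's post-onset transitions. Node visit
#' probabilities are the fraction of runs that entered the subspace after
#' onset; edge probabilities are conditional on leaving the source node.
#'
#' @param ens a \code{wta_ensemble}.
#' @return List of class \code{wta_transition_graph} with data frames
#'   \code{nodes} (pattern, divergence, klass, visits, visit_prob) and
#'   \code{edges} (from, to, count, probability, gradient_sign).
#' @export
transition_graph <- function(ens) {
  stopifnot(inherits(ens, "wta_ensemble"))
  tr <- ens$transitions
  net <- ens$net
  keys <- unique(c(tr$from, tr$to))
  if (length(keys) == 0) {
    nodes <- data.frame(pattern = character(0), divergence = numeric(0),
                        klass = character(0), visits = integer(0),
                        visit_prob = numeric(0), stringsAsFactors = FALSE)
    edges <- data.frame(from = character(0), to = character(0),
                        count = integer(0), probability = numeric(0),
                        gradient_sign = character(0), stringsAsFactors = FALSE)
    return(structure(list(nodes = nodes, edges = edges),
                     class = "wta_transition_graph"))
  }
  info <- lapply(keys, function(k) classify_subspace(net, key_to_pattern(k)))
  # visits: number of distinct runs seen at the node (as source or target)
  visits <- vapply(keys, function(k) {
    length(unique(tr$run[tr$from == k | tr$to == k]))
  }, integer(1))
  nodes <- data.frame(
    pattern = keys,
    divergence = vapply(info, function(s) s$divergence, numeric(1)),
    klass = vapply(info, function(s) s$klass, character(1)),
    visits = visits,
    visit_prob = visits / ens$n_runs,
    stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$divergence), ]
  rownames(nodes) <- NULL

  ek <- paste(tr$from, tr$to, sep = ">")
  agg <- as.data.frame(table(ek), stringsAsFactors = FALSE)
  parts <- strsplit(agg$ek, ">", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                      to = vapply(parts, `[`, character(1), 2L),
                      count = agg$Freq, stringsAsFactors = FALSE)
  out_tot <- tapply(edges$count, edges$from, sum)
  edges$probability <- edges$count / as.numeric(out_tot[edges$from])
  div_of <- stats::setNames(nodes$divergence, nodes$pattern)
  edges$gradient_sign <- ifelse(div_of[edges$to] > div_of[edges$from],
                                "increasing", "decreasing")
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "wta_transition_graph")
}

#' @export
print.wta_transition_graph <- function(x, ...) {
  cat("wta_transition_graph:", nrow(x$nodes), "subspaces,",
      nrow(x$edges), "distinct transitions (",
      sum(x$edges$gradient_sign == "increasing"), "against-gradient )\n")
  invisible(x)
}

#' Convert a transition graph to igraph
#'
#' Node attributes: divergence, klass, visit_prob; edge attributes: count,
#' probability, gradient_sign. Write to GraphML or DOT with
#' \code{igraph::write_graph()}.
#'
#' @param graph a \code{wta_transition_graph}.
#' @return An \code{igraph} object.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "wta_transition_graph"))
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for graph export", call. = FALSE)
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = graph$nodes)
}

#' Entropy curves as a function of network gain
#'
#' Rebuilds the WTA with each self-excitation value in \code{alphas}
#' (skipping, with a warning, values violating the contraction bounds),
#' runs an ensemble per gain, and summarises each entropy curve by its time
#' to peak, peak height, and asymptote (entropy at the final recorded
#' step). Higher gain speeds up both the rise and the decay of entropy but
#' leaves the asymptote unchanged when all permitted subspaces remain
#' equally likely.
#'
#' @param alphas self-excitation values to sweep.
#' @param n_exc excitatory units in each network.
#' @param params base parameter set (alpha1 is overridden per sweep point).
#' @param protocol input protocol template.
#' @param n_runs,n_steps,seed,record_stride passed to
#'   \code{\link{run_ensemble}}.
#' @return List with \code{curves} (named list of entropy data frames) and
#'   \code{summary} (data frame: alpha1, gain, time_to_peak, peak_H,
#'   asymptote_H).
#' @export
gain_sweep <- function(alphas, n_exc = 4, params = network_params(),
                       protocol = input_protocol(input_sigma = 0.25),
                       n_runs = 1000, n_steps = 10000, seed = 1,
                       record_stride = 100) {
  curves <- list()
  rows <- list()
  for (a in alphas) {
    p <- params; p$alpha1 <- a
    if (length(validate_params(p)) > 0) {
      warning("alpha1 = ", a, " violates the contraction bounds; skipped",
              call. = FALSE)
      next
    }
    net <- build_wta(n_exc, p)
    ens <- run_ensemble(net, protocol, n_runs = n_runs, seed = seed,
                        n_steps = n_steps, record_stride = record_stride)
    H <- ens$entropy
    nm <- paste0("alpha1=", a)
    curves[[nm]] <- H
    rows[[nm]] <- data.frame(alpha1 = a, gain = wta_gain(p),
                             time_to_peak = H$step[which.max(H$H)],
                             peak_H = max(H$H),
                             asymptote_H = H$H[nrow(H)])
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(curves = curves, summary = summary)
}

#' Time to first permitted subspace versus grid size
#'
#' For each grid side length, assembles fresh random grid networks (one per
#' run, seeded from the master seed), simulates each under constant random
#' inputs, and records the first post-onset step at which the network's
#' activation pattern classifies as permitted (full-pattern mode). Runs
#' that never reach a permitted subspace within the budget are counted as
#' censored, never dropped silently.
#'
#' Convergence to a permitted subspace is guaranteed only when every
#' excitatory unit participates in at least one inhibitory loop: an
#' isolated self-exciting unit keeps a positive eigenvalue in every active
#' set it belongs to, so a run containing one can never classify as
#' permitted. With \code{require_bounded = TRUE} (default) grids are
#' redrawn (deterministically, from derived seeds) until no excitatory
#' unit is isolated, sampling the population of dynamically bounded
#' networks; with \code{FALSE} the raw occupancy sampling is used and
#' isolated-unit runs end up censored.
#'
#' @param sides vector of grid side lengths (>= 2).
#' @param runs_per_side simulated runs (and fresh grids) per side.
#' @param seed master RNG seed.
#' @param params motif parameters for the grids.
#' @param protocol input protocol template (default: constant inputs
#'   N(6,1) at step 2000, no noise).
#' @param budget_steps censoring budget after onset (default 12000 steps,
#'   i.e. 120 time constants; generous so that slow large-grid runs are
#'   measured rather than censored, which would bias means downward).
#' @param record_stride recording stride for the underlying runs.
#' @param require_bounded redraw grids until no excitatory unit lacks an
#'   inhibitory partner (see Details).
#' @return Data frame: side, n_runs, n_censored, mean_time, sd_time (steps
#'   after onset, over non-censored runs).
#' @export
time_to_permitted_vs_size <- function(sides, runs_per_side = 100, seed = 1,
                                      params = network_params(),
                                      protocol = input_protocol(),
                                      budget_steps = 12000,
                                      record_stride = 100,
                                      require_bounded = TRUE) {
  stopifnot(all(sides >= 2))
  set.seed(seed)
  grid_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  length(sides) * runs_per_side),
                       nrow = length(sides))
  n_steps <- protocol$onset_step + budget_steps
  rows <- list()
  for (si in seq_along(sides)) {
    times <- rep(NA_real_, runs_per_side)
    censored <- logical(runs_per_side)
    for (r in seq_len(runs_per_side)) {
      net <- draw_grid(sides[si], params, grid_seeds[si, r], require_bounded)
      if (net$n == 0L || sum(net$types == "exc") == 0L) {
        times[r] <- 0  # nothing to compete: off/permitted immediately
        next
      }
      ens <- run_ensemble(net, protocol, n_runs = 1,
                          seed = grid_seeds[si, r] %% 1000000L + 1L,
                          n_steps = n_steps, record_stride = record_stride,
                          mode = "full", budget_steps = budget_steps)
      if (ens$censored[1]) censored[r] <- TRUE
      else times[r] <- ens$time_to_permitted[1]
    }
    ok <- !censored & !is.na(times)
    rows[[si]] <- data.frame(side = sides[si], n_runs = runs_per_side,
                             n_censored = sum(censored),
                             mean_time = mean(times[ok]),
                             sd_time = stats::sd(times[ok]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Draw a grid; optionally redraw (derived seeds) until every excitatory
# unit has at least one inhibitory partner.
draw_grid <- function(side, params, seed, require_bounded, max_tries = 1000L) {
  for (k in seq_len(max_tries)) {
    sk <- as.integer((as.numeric(seed) + 7919 * (k - 1)) %% (2^31 - 1))
    net <- suppressWarnings(build_random_grid(
      grid_spec(side = side, params = params, seed = sk)))
    if (!require_bounded) return(net)
    exc <- which(net$types == "exc")
    inh <- which(net$types == "inh")
    if (length(exc) == 0L) return(net)
    if (length(inh) > 0L &&
        all(vapply(exc, function(i) any(net$W[i, inh] != 0), logical(1))))
      return(net)
  }
  stop("no bounded grid found in ", max_tries, " draws", call. = FALSE)
}
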