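#' Write a network to a JSON file
#'
#' Serialises the network as
#' \code{{"types": [...], "W": [[...]], "G": [...], "tau": ...}} plus
#' labels, motif parameters and grid coordinates when present. Numbers are
#' written at full precision, so a round trip reproduces the network
#' bit-exactly.
#'
#' @param net a \code{wta_network}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "wta_network"))
  obj <- list(types = net$types, W = net$W, G = net$G, tau = net$tau)
  if (!is.null(net$labels)) obj$labels <- net$labels
  if (!is.null(net$params)) obj$params <- unclass(net$params)
  if (!is.null(net$coords)) obj$coords <- net$coords
  if (isTRUE(net$unbounded)) obj$unbounded <- TRUE
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network from a JSON file
#'
#' @param path file written by \code{\link{write_network}} (or hand-made
#'   with the same keys).
#' @return A \code{wta_network}; connectivity sign conventions are
#'   re-validated on load.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("types", "W", "G", "tau"))
    if (is.null(obj[[k]])) stop("network file misses key '", k, "'", call. = FALSE)
  W <- as.matrix(obj$W)
  params <- if (!is.null(obj$params)) do.call(network_params, obj$params) else NULL
  new_wta_network(length(obj$G), obj$types, W, obj$G, obj$tau,
                  labels = obj$labels, params = params,
                  coords = if (!is.null(obj$coords)) as.matrix(obj$coords) else NULL,
                  unbounded = isTRUE(obj$unbounded))
}

#' Write a trajectory as TSV
#'
#' Columns: \code{step}, \code{x_1..x_n}, \code{I_1..I_n}, \code{pattern}
#' (bitstring over all units), one row per recorded step.
#'
#' @param tr a \code{wta_trajectory} recorded with
#'   \code{record_state = TRUE}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(tr, path) {
  stopifnot(inherits(tr, "wta_trajectory"))
  if (is.null(tr$X)) stop("trajectory was recorded without state", call. = FALSE)
  n <- ncol(tr$X)
  # 17 significant digits so a numeric round trip is bit-exact
  fmt <- function(m) apply(m, 2, function(col) sprintf("%.17g", col))
  d <- data.frame(step = tr$steps, fmt(tr$X), fmt(tr$I),
                  pattern = pattern_keys(tr$active),
                  stringsAsFactors = FALSE)
  names(d) <- c("step", paste0("x_", seq_len(n)), paste0("I_", seq_len(n)),
                "pattern")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory TSV back into its data frame form
#'
#' @param path TSV written by \code{\link{write_trajectory}}.
#' @return Data frame with the same columns (pattern as character).
#' @export
read_trajectory <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = list(pattern = "character"),
                    stringsAsFactors = FALSE)
}

#' Write the transition log of a trajectory as CSV
#'
#' Columns \code{step}, \code{from_pattern}, \code{to_pattern}.
#'
#' @param tr a \code{wta_trajectory}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_transitions <- function(tr, path) {
  stopifnot(inherits(tr, "wta_trajectory"))
  d <- tr$transitions
  names(d) <- c("step", "from_pattern", "to_pattern")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_defaults <- list(
  network = NULL, builder = NULL,
  steps = 10000L, onset = 2000L, dt = 0.01,
  input_mu = 6, input_sigma = 1, noise_sigma = 0,
  noise_resample_period = 100L,
  runs = 1L, seed = 1L, record_stride = 1L,
  subspace_mode = "excitatory", out_prefix = "run")

#' Load a run configuration
#'
#' Reads a JSON run configuration, fills in the documented defaults
#' (Euler step 0.01, onset step 2000, inputs N(6,1), noise off), and
#' errors on unknown keys rather than ignoring them. The configuration
#' must name either a \code{network} file or a \code{builder}
#' specification (\code{{"type": "wta", "n_exc": ...}} or
#' \code{{"type": "grid", "side": ...}}, each with optional motif
#' parameters under \code{"params"}).
#'
#' @param path JSON file path.
#' @return A \code{wta_run_config}: the resolved option list plus the
#'   loaded/built \code{network}.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), names(config_defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(config_defaults, raw)
  if (is.null(cfg$network) && is.null(cfg$builder))
    stop("config must provide 'network' (file) or 'builder'", call. = FALSE)
  net <- if (!is.null(cfg$network)) {
    read_network(cfg$network)
  } else {
    b <- cfg$builder
    p <- if (!is.null(b$params)) do.call(network_params, b$params)
         else network_params()
    switch(b$type,
           wta = build_wta(b$n_exc, p),
           grid = build_random_grid(grid_spec(
             side = b$side,
             p_occupied = b$p_occupied %||% 0.4,
             p_exc = b$p_exc %||% 0.8,
             max_inh_partners = b$max_inh_partners %||% 8,
             p_connect = b$p_connect %||% 0.4,
             params = p, seed = b$seed %||% cfg$seed)),
           stop("unknown builder type '", b$type, "'", call. = FALSE))
  }
  if (cfg$subspace_mode == "excitatory" && sum(net$types == "inh") > 1L)
    warning("network has several inhibitory units; ",
            "subspace_mode = \"full\" is recommended", call. = FALSE)
  cfg$network_object <- net
  structure(cfg, class = "wta_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save analysis outputs with a checksummed manifest
#'
#' Writes the files appropriate to the result class -- trajectory (TSV +
#' transitions CSV), ensemble (entropy, occupancy, transitions, graph
#' nodes/edges CSV), or subspace table (CSV) -- under
#' \code{<prefix>_<name>} and a JSON manifest \code{<prefix>_manifest.json}
#' listing every file with its MD5 checksum.
#'
#' @param result a \code{wta_trajectory}, \code{wta_ensemble}, or
#'   \code{wta_subspace_table}.
#' @param prefix output path prefix.
#' @return Data frame manifest (file, md5), invisibly.
#' @export
save_outputs <- function(result, prefix) {
  files <- character(0)
  w <- function(fun, suffix, ...) {
    f <- paste0(prefix, suffix)
    fun(..., f)
    files <<- c(files, f)
  }
  wcsv <- function(d, suffix) {
    f <- paste0(prefix, suffix)
    utils::write.csv(d, f, row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
  }
  if (inherits(result, "wta_trajectory")) {
    if (!is.null(result$X)) w(write_trajectory, "_trajectory.tsv", result)
    w(write_transitions, "_transitions.csv", result)
  } else if (inherits(result, "wta_ensemble")) {
    wcsv(result$entropy, "_entropy.csv")
    wcsv(result$occupancy, "_occupancy.csv")
    wcsv(result$transitions, "_transitions.csv")
    wcsv(result$graph$nodes, "_graph_nodes.csv")
    wcsv(result$graph$edges, "_graph_edges.csv")
  } else if (inherits(result, "wta_subspace_table")) {
    wcsv(as.data.frame(result), "_subspaces.csv")
  } else {
    stop("unsupported result class", call. = FALSE)
  }
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  mf <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
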