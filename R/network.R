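#' Triangular samples on the interval from zero to an upper bound
#'
#' Draws from the triangular distribution with support `[0, upper]` and mode
#' at `mode_fraction * upper`.  All per-neuron and per-synapse parameters of
#' the model (basic activity, synaptic strengths) are drawn this way, so that
#' the configured value acts as an upper bound rather than a shared constant.
#'
#' @param n number of draws.
#' @param upper upper end of the support; must be `>= 0`.  `upper = 0`
#'   degenerates to a point mass at zero.
#' @param mode_fraction position of the mode as a fraction of `upper`,
#'   in `[0, 1]`.  The default 1 puts the mode at the upper bound.
#' @return numeric vector of `n` draws in `[0, upper]`.
#' @examples
#' set.seed(1)
#' mean(sample_triangular(1e4, 0.9))  # close to 2/3 * 0.9
#' @export
sample_triangular <- function(n, upper, mode_fraction = 1) {
  if (!is.numeric(upper) || length(upper) != 1L || is.na(upper) || upper < 0)
    stop("`upper` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(mode_fraction) || length(mode_fraction) != 1L ||
      is.na(mode_fraction) || mode_fraction < 0 || mode_fraction > 1)
    stop("`mode_fraction` must be in [0, 1]", call. = FALSE)
  if (n == 0L) return(numeric(0))
  if (upper == 0) return(rep(0, n))
  b <- upper
  m <- mode_fraction * b
  u <- runif(n)
  # inverse CDF of triangular(0, b, mode m)
  lo <- u < m / b
  out <- numeric(n)
  out[lo] <- sqrt(u[lo] * b * m)
  out[!lo] <- b - sqrt((1 - u[!lo]) * b * (b - m))
  out
}

#' Parameter upper bounds of the model
#'
#' The three bounds from which per-neuron basic activity and per-synapse
#' strengths are drawn.  All values lie between zero and one in magnitude;
#' the inhibitory bound is stored as a negative number.
#'
#' @param c_upper upper bound of the basic activity `c_i`, in `[0, 1]`.
#' @param y_exc_upper upper bound of excitatory synaptic strength, in `[0, 1]`.
#' @param y_inh_upper bound of inhibitory synaptic strength, in `[-1, 0]`
#'   (a negative value; its magnitude is the triangular upper bound).
#' @return an object of class `parameter_bounds`.
#' @export
parameter_bounds <- function(c_upper, y_exc_upper, y_inh_upper) {
  stopifnot(is.numeric(c_upper), length(c_upper) == 1L,
            is.numeric(y_exc_upper), length(y_exc_upper) == 1L,
            is.numeric(y_inh_upper), length(y_inh_upper) == 1L)
  if (c_upper < 0 || c_upper > 1)
    stop("`c_upper` must lie in [0, 1]", call. = FALSE)
  if (y_exc_upper < 0 || y_exc_upper > 1)
    stop("`y_exc_upper` must lie in [0, 1]", call. = FALSE)
  if (y_inh_upper > 0 || y_inh_upper < -1)
    stop("`y_inh_upper` must lie in [-1, 0]", call. = FALSE)
  structure(list(c_upper = c_upper, y_exc_upper = y_exc_upper,
                 y_inh_upper = y_inh_upper),
            class = "parameter_bounds")
}

#' @export
print.parameter_bounds <- function(x, ...) {
  cat(sprintf("parameter bounds: c <= %g, y+ <= %g, y- >= %g\n",
              x$c_upper, x$y_exc_upper, x$y_inh_upper))
  invisible(x)
}

#' Specification of a random excitatory/inhibitory network
#'
#' @param n_neurons number of neurons (>= 1).
#' @param connection_probability probability that any ordered pair (j, i),
#'   j != i, is connected; autapses never occur.
#' @param bounds a [parameter_bounds()] object.
#' @param inhibitory_fraction fraction of inhibitory neurons; the count is
#'   deterministic, `round(n_neurons * inhibitory_fraction)`.  Default 0.2
#'   (the usual 80/20 excitatory/inhibitory split of cortical tissue).
#' @param triangular_mode_fraction mode position for all triangular draws,
#'   as a fraction of the respective bound (default 1, mode at the bound).
#' @param seed integer seed making the network reproducible.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(n_neurons, connection_probability, bounds,
                         inhibitory_fraction = 0.2,
                         triangular_mode_fraction = 1,
                         seed = 1L) {
  stopifnot(is.numeric(n_neurons), length(n_neurons) == 1L, n_neurons >= 1)
  if (connection_probability < 0 || connection_probability > 1)
    stop("`connection_probability` must lie in [0, 1]", call. = FALSE)
  if (inhibitory_fraction < 0 || inhibitory_fraction > 1)
    stop("`inhibitory_fraction` must lie in [0, 1]", call. = FALSE)
  if (!inherits(bounds, "parameter_bounds"))
    bounds <- do.call(parameter_bounds, as.list(bounds))
  structure(list(n_neurons = as.integer(n_neurons),
                 inhibitory_fraction = inhibitory_fraction,
                 connection_probability = connection_probability,
                 bounds = bounds,
                 triangular_mode_fraction = triangular_mode_fraction,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Generate a random excitatory/inhibitory network
#'
#' Every ordered pair (j, i) with j != i receives a directed connection
#' independently with the spec's connection probability (no autapses).  Each
#' connection strength is drawn from a triangular distribution on
#' `[0, bound]` of the presynaptic type (negated for inhibitory presynaptic
#' neurons), and each neuron's basic activity from `[0, c_upper]`.  Exactly
#' `round(n * inhibitory_fraction)` neurons, chosen at random, are
#' inhibitory.  The result is bit-for-bit reproducible from the spec's seed.
#'
#' @param spec a [network_spec()].
#' @return an object of class `inex_network`: list with `neuron_types`
#'   (character, "excitatory"/"inhibitory"), `basic_activity` (numeric c_i),
#'   `weights` (sparse `dgCMatrix`, rows = presynaptic j, cols =
#'   postsynaptic i) and `spec`.
#' @examples
#' net <- generate_network(network_spec(50, 0.1,
#'   parameter_bounds(0.07, 0.5, -0.1), seed = 42))
#' Matrix::nnzero(net$weights)
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  n <- spec$n_neurons
  n_inh <- round(n * spec$inhibitory_fraction)
  types <- rep("excitatory", n)
  if (n_inh > 0) types[sample.int(n, n_inh)] <- "inhibitory"

  # i.i.d. Bernoulli over the n(n-1) ordered pairs, sampled as a binomial
  # count followed by a uniform draw of pair indices without replacement
  n_pairs <- n * (n - 1)
  p <- spec$connection_probability
  m <- if (p >= 1) n_pairs else if (p <= 0) 0L else rbinom(1L, n_pairs, p)
  if (m > 0) {
    idx <- if (m == n_pairs) seq_len(n_pairs) else sort(sample.int(n_pairs, m))
    j <- (idx - 1L) %/% (n - 1L) + 1L
    r <- (idx - 1L) %% (n - 1L) + 1L
    i <- r + (r >= j)
    z <- sample_triangular(m, 1, spec$triangular_mode_fraction)
    exc <- types[j] == "excitatory"
    w <- ifelse(exc, spec$bounds$y_exc_upper * z, spec$bounds$y_inh_upper * z)
  } else {
    j <- i <- integer(0); w <- numeric(0)
  }
  weights <- Matrix::sparseMatrix(i = j, j = i, x = w, dims = c(n, n))
  basic <- spec$bounds$c_upper *
    sample_triangular(n, 1, spec$triangular_mode_fraction)

  structure(list(neuron_types = types, basic_activity = basic,
                 weights = weights, spec = spec),
            class = "inex_network")
}

#' @export
print.inex_network <- function(x, ...) {
  n <- length(x$neuron_types)
  cat(sprintf(paste0("<inex_network> %d neurons (%d inhibitory), ",
                     "%d connections (density %.4f)\n"),
              n, sum(x$neuron_types == "inhibitory"),
              Matrix::nnzero(x$weights),
              Matrix::nnzero(x$weights) / (n * (n - 1))))
  invisible(x)
}

#' Write / read a network as JSON
#'
#' The document stores neuron types, basic activities, an edge list
#' `[j, i, weight]` (1-based indices) and the generating spec, which is
#' enough to reconstruct the network exactly.
#'
#' @param network an `inex_network`.
#' @param path file path.
#' @return `read_network()` returns the reconstructed `inex_network`;
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "inex_network"))
  tw <- Matrix::summary(network$weights)
  doc <- list(
    neuron_types = network$neuron_types,
    basic_activity = network$basic_activity,
    edges = unname(cbind(tw$i, tw$j, tw$x)),
    spec = c(unclass(network$spec[c("n_neurons", "inhibitory_fraction",
                                    "connection_probability",
                                    "triangular_mode_fraction", "seed")]),
             list(bounds = unclass(network$spec$bounds)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(doc$neuron_types)
  e <- doc$edges
  weights <- if (is.matrix(e) && nrow(e) > 0) {
    Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = e[, 3], dims = c(n, n))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, n))
  }
  spec <- network_spec(doc$spec$n_neurons, doc$spec$connection_probability,
                       do.call(parameter_bounds, doc$spec$bounds),
                       inhibitory_fraction = doc$spec$inhibitory_fraction,
                       triangular_mode_fraction = doc$spec$triangular_mode_fraction,
                       seed = doc$spec$seed)
  structure(list(neuron_types = doc$neuron_types,
                 basic_activity = doc$basic_activity,
                 weights = weights, spec = spec),
            class = "inex_network")
}
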