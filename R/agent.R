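#' Hyperparameters of the dual-module agent
#'
#' @param lambda weight of the ring-regularization term (must be > 0).
#' @param r2 squared ring radius; the zero-loss solutions sit at
#'   `delta_z = theta = +/- sqrt(r2 / 2)`.
#' @param lr learning rate of plain (vanilla) SGD.
#' @param batch_pairs image pairs per batch.
#' @param steps_per_batch gradient steps applied to each batch.
#' @return a list of class `dual_hyper`.
#' @export
dual_hyper <- function(lambda = 4, r2 = 0.1, lr = 0.004,
                       batch_pairs = 2L, steps_per_batch = 20L) {
  stopifnot(lambda > 0, r2 > 0, lr > 0, batch_pairs >= 1, steps_per_batch >= 1)
  structure(list(lambda = lambda, r2 = r2, lr = lr,
                 batch_pairs = as.integer(batch_pairs),
                 steps_per_batch = as.integer(steps_per_batch)),
            class = "dual_hyper")
}

# Layer geometry for a given input side; flat is the flattened length fed to
# the final linear layer (2592 at the default side of 224).
net_dims <- function(side) cpp_net_dims(as.integer(side))

#' Initialize a dual-module agent
#'
#' The representational module is a convolutional encoder mapping a 3-channel
#' square image to one scalar; the relational module is the single scalar
#' `theta` holding the expected representation difference. All encoder
#' weights and biases are drawn uniformly on `[-1/sqrt(N), 1/sqrt(N)]` where
#' `N` is the layer's fan-in; `theta` follows the same rule for a one-input
#' unit, i.e. uniform on `[-1, 1]`.
#'
#' @param seed integer seed for the initialization draw.
#' @param side input image side in pixels (default 224, for which the
#'   flattened pre-linear activation has 2592 entries).
#' @return an object of class `dual_agent`: list with the flat parameter
#'   vector `par`, the `side`, layer geometry `dims`, and `seed`.
#' @export
dual_agent <- function(seed = NULL, side = 224L) {
  side <- as.integer(side)
  d <- net_dims(side)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(as.integer(seed))
  }
  layer <- function(n, fan_in) stats::runif(n, -1 / sqrt(fan_in), 1 / sqrt(fan_in))
  par <- c(
    layer(16 * 12, 12), layer(16, 12),        # conv1 weights + biases
    layer(32 * 64, 64), layer(32, 64),        # conv2
    layer(32 * 288, 288), layer(32, 288),     # conv3
    layer(d[["flat"]], d[["flat"]]), layer(1, d[["flat"]]),  # linear
    stats::runif(1, -1, 1))                   # theta (fan-in 1)
  structure(list(par = par, side = side, dims = d,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "dual_agent")
}

#' @export
print.dual_agent <- function(x, ...) {
  cat("Dual-module agent\n")
  cat(sprintf("  input: %d x %d (3 replicated channels)   parameters: %d\n",
              x$side, x$side, length(x$par)))
  cat(sprintf("  flattened encoder output: %d -> 1\n", x$dims[["flat"]]))
  cat(sprintf("  theta = %.4f\n", agent_theta(x)))
  invisible(x)
}

#' Relational parameter of an agent
#' @param agent a [dual_agent()].
#' @return the scalar theta.
#' @export
agent_theta <- function(agent) agent$par[length(agent$par)]

#' Encode images to their scalar representations
#'
#' @param agent a [dual_agent()].
#' @param images a `side x side` matrix or a `side x side x n` array of
#'   grayscale images in `[0,1]` (replicated to 3 channels internally).
#' @return numeric vector of Z values, one per image.
#' @export
encode <- function(agent, images) {
  stopifnot(inherits(agent, "dual_agent"))
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  stopifnot(dim(images)[1] == agent$side, dim(images)[2] == agent$side)
  cpp_forward_batch(agent$par, agent$side, as.numeric(images), dim(images)[3])
}

#' Representation difference for an image pair
#'
#' `delta_z = Z(right) - Z(left)`; antisymmetric under swapping the images.
#'
#' @param agent a [dual_agent()].
#' @param pair an [sample_pair()] result (rendered).
#' @return scalar difference of the two encodings.
#' @export
delta_z <- function(agent, pair) {
  stopifnot(inherits(pair, "image_pair"), !is.null(pair$left_image))
  z <- encode(agent, array(c(pair$left_image, pair$right_image),
                           c(agent$side, agent$side, 2L)))
  z[2] - z[1]
}

#' Ring-regularized pair loss
#'
#' `(dz - theta)^2 + lambda * (dz^2 + theta^2 - r2)^2`. The quadratic term
#' pulls the representation difference towards the expected relation; the
#' ring term forbids the collapsed solution `dz = theta = 0`. The loss is
#' zero exactly at `dz = theta = +/- sqrt(r2/2)`.
#'
#' @param dz representation difference.
#' @param theta relational parameter.
#' @param hyper a [dual_hyper()].
#' @return non-negative scalar (vectorized over `dz`/`theta`).
#' @export
ring_loss <- function(dz, theta, hyper = dual_hyper()) {
  (dz - theta)^2 + hyper$lambda * (dz^2 + theta^2 - hyper$r2)^2
}

#' Pair loss of an agent on an image pair
#'
#' @inheritParams delta_z
#' @param hyper a [dual_hyper()].
#' @return the [ring_loss()] at the agent's `delta_z` and `theta`.
#' @export
pair_loss <- function(agent, pair, hyper = dual_hyper()) {
  ring_loss(delta_z(agent, pair), agent_theta(agent), hyper)
}

#' Order decision for a presented pair
#'
#' The agent evaluates the loss of the pair as presented and of the swapped
#' order (which negates `delta_z`) and judges the presented order correct iff
#' its loss is strictly smaller; exact ties are judged incorrect.
#'
#' @inheritParams pair_loss
#' @return logical.
#' @export
order_decision <- function(agent, pair, hyper = dual_hyper()) {
  dz <- delta_z(agent, pair)
  th <- agent_theta(agent)
  ring_loss(dz, th, hyper) < ring_loss(-dz, th, hyper)
}

#' Evaluate an agent on a set of pairs
#'
#' @param agent a [dual_agent()].
#' @param pairs list of rendered [sample_pair()] objects (e.g. the `test`
#'   element of an [make_phase()] result).
#' @param hyper a [dual_hyper()].
#' @return list with `accuracy` (fraction of correct order decisions),
#'   `mean_dz` (mean representation difference), `dz` (per-pair values) and
#'   `theta`.
#' @export
evaluate_agent <- function(agent, pairs, hyper = dual_hyper()) {
  arr <- pair_arrays(pairs)
  res <- cpp_evaluate(agent$par, agent$side, as.numeric(arr$left),
                      as.numeric(arr$right), length(pairs),
                      hyper$lambda, hyper$r2)
  res[c("accuracy", "mean_dz", "dz", "theta")]
}

#' Save / load an agent checkpoint
#'
#' The checkpoint is self-describing: it stores the parameter vector together
#' with the input geometry and the initialization seed.
#'
#' @param agent a [dual_agent()].
#' @param path file path.
#' @return `load_agent` returns the restored `dual_agent`.
#' @export
save_agent <- function(agent, path) {
  stopifnot(inherits(agent, "dual_agent"))
  saveRDS(unclass(agent), path)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) {
  obj <- readRDS(path)
  structure(obj, class = "dual_agent")
}
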