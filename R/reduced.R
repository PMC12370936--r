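# Reduced scalar model: the image pair is replaced by a scalar pair differing
# by the rule alpha, the encoder by a single weight w (so delta_z = w * alpha),
# and learning by the gradient flow of the ring-regularized loss
#   L(dz, theta) = (dz - theta)^2 + lambda * (dz^2 + theta^2 - r^2)^2
# in the (delta_z, theta) plane:
#   d(dz)/dt    = alpha^2 * [ (theta - dz) - 2 lambda (dz^2 + theta^2 - r^2) dz ]
#   d(theta)/dt =            (dz - theta) - 2 lambda (dz^2 + theta^2 - r^2) theta
# The alpha^2 prefactor is the relative adaptation speed of the
# representational module.

#' Reduced-model loss surface
#'
#' @param dz,theta state coordinates (vectorized).
#' @param lambda regularization weight.
#' @param r2 squared ring radius.
#' @return loss values.
#' @export
reduced_loss <- function(dz, theta, lambda, r2) {
  (dz - theta)^2 + lambda * (dz^2 + theta^2 - r2)^2
}

#' Gradient-flow vector field of the reduced model
#'
#' @param state numeric `c(dz, theta)`.
#' @param alpha rule magnitude (its square scales the `dz` component).
#' @param lambda regularization weight (`0` gives the unregularized flow).
#' @param r2 squared ring radius.
#' @return numeric `c(d_dz, d_theta)`.
#' @export
reduced_flow <- function(state, alpha, lambda, r2) {
  dz <- state[1]; theta <- state[2]
  ring <- dz^2 + theta^2 - r2
  c(alpha^2 * ((theta - dz) - 2 * lambda * ring * dz),
    (dz - theta) - 2 * lambda * ring * theta)
}

#' Integrate the reduced model to convergence
#'
#' Adaptive integration (lsodar, absolute/relative tolerance 1e-9) that stops
#' when the flow norm drops below `tol` or the horizon is reached. The
#' terminal state is matched against the model's fixed points.
#'
#' @param state0 numeric `c(dz, theta)` start.
#' @param alpha rule magnitude.
#' @param lambda regularization weight.
#' @param r2 squared ring radius.
#' @param t_max integration horizon (time units of the flow).
#' @param tol convergence threshold on the flow norm.
#' @param n_save number of saved time points.
#' @return an object of class `reduced_trajectory`: list with `times`,
#'   `states` (matrix with columns `dz`, `theta`), `terminal`, `converged`,
#'   `fixed_point` (row of [find_fixed_points()] the terminal state is within
#'   `1e-3` of, or `NA`), and the parameters.
#' @export
reduced_integrate <- function(state0, alpha, lambda, r2,
                              t_max = 1e4, tol = 1e-8, n_save = 400L) {
  stopifnot(length(state0) == 2, is.finite(state0), alpha > 0,
            lambda >= 0, r2 > 0)
  deriv <- function(t, y, parms) list(reduced_flow(y, alpha, lambda, r2))
  rootfun <- function(t, y, parms) {
    sqrt(sum(reduced_flow(y, alpha, lambda, r2)^2)) - tol
  }
  times <- c(0, exp(seq(log(1e-3), log(t_max), length.out = n_save - 1L)))
  sol <- deSolve::lsodar(y = c(dz = state0[1], theta = state0[2]),
                         times = times, func = deriv, parms = NULL,
                         rootfunc = rootfun, atol = 1e-9, rtol = 1e-9)
  states <- unname(sol[, 2:3, drop = FALSE])
  colnames(states) <- c("dz", "theta")
  terminal <- states[nrow(states), ]
  converged <- sqrt(sum(reduced_flow(terminal, alpha, lambda, r2)^2)) <= tol * 1.01
  fp <- NA_character_
  if (lambda > 0) {
    fps <- find_fixed_points(lambda, r2)
    dist <- sqrt((fps$dz - terminal[1])^2 + (fps$theta - terminal[2])^2)
    if (any(dist < 1e-3)) fp <- rownames(fps)[which.min(dist)]
  }
  structure(list(times = unname(sol[, 1]), states = states,
                 terminal = terminal, converged = converged,
                 fixed_point = fp, alpha = alpha, lambda = lambda, r2 = r2),
            class = "reduced_trajectory")
}

#' @export
print.reduced_trajectory <- function(x, ...) {
  cat(sprintf("Reduced-model trajectory (alpha = %g, lambda = %g, r2 = %g)\n",
              x$alpha, x$lambda, x$r2))
  cat(sprintf("  start (%.4f, %.4f) -> terminal (%.4f, %.4f)%s%s\n",
              x$states[1, 1], x$states[1, 2], x$terminal[1], x$terminal[2],
              if (x$converged) ", converged" else ", horizon reached",
              if (!is.na(x$fixed_point)) paste0(" at ", x$fixed_point) else ""))
  invisible(x)
}

#' Terminal point on the line attractor of the unregularized flow
#'
#' With `lambda = 0` the two flow equations are linearly dependent:
#' `dz + alpha^2 * theta` is conserved and every point of the line
#' `dz = theta` is neutrally stable, so the system relaxes to
#' `dz = theta = (alpha^2 * theta0 + dz0) / (alpha^2 + 1)`.
#'
#' @param dz0,theta0 initial state.
#' @param alpha rule magnitude.
#' @return the common terminal value of `dz` and `theta`.
#' @export
line_attractor_point <- function(dz0, theta0, alpha) {
  (alpha^2 * theta0 + dz0) / (alpha^2 + 1)
}

#' Line-attractor endpoint after a general rule change alpha1 -> -alpha2
#'
#' Starting from the positive solution of phase 1 (`w* = r / (sqrt(2) *
#' alpha1)`), the post-switch state is `dz(0) = -(r / sqrt(2)) * (alpha2 /
#' alpha1)`, `theta(0) = r / sqrt(2)`, and the unregularized flow relaxes to
#' `dz = theta = (r / sqrt(2)) * (alpha2^2 - alpha2 / alpha1) / (alpha2^2 + 1)`.
#' The sign is positive (representational adaptation: `theta` keeps its sign)
#' iff `alpha1 * alpha2 > 1`.
#'
#' @param alpha1,alpha2 positive rule magnitudes before and after the switch.
#' @param r ring radius.
#' @return the common terminal value of `dz` and `theta`.
#' @export
general_endpoint <- function(alpha1, alpha2, r) {
  stopifnot(alpha1 > 0, alpha2 > 0)
  (r / sqrt(2)) * (alpha2^2 - alpha2 / alpha1) / (alpha2^2 + 1)
}

# Jacobian of the reduced flow (analytic linearization).
reduced_jacobian <- function(state, alpha, lambda, r2) {
  dz <- state[1]; th <- state[2]
  ring <- dz^2 + th^2 - r2
  j11 <- alpha^2 * (-1 - 2 * lambda * (ring + 2 * dz^2))
  j12 <- alpha^2 * (1 - 4 * lambda * dz * th)
  j21 <- 1 - 4 * lambda * dz * th
  j22 <- -1 - 2 * lambda * (ring + 2 * th^2)
  matrix(c(j11, j21, j12, j22), 2, 2)
}

#' Fixed points of the reduced model and their stability
#'
#' The flow always has the unstable origin and the two stable solutions
#' `dz = theta = +/- r / sqrt(2)` on the ring. When the regularization is
#' strong (`lambda > 1 / r2`) an additional unstable anti-diagonal pair
#' `dz = -theta = +/- sqrt((r2 - 1/lambda) / 2)` appears. Stability is
#' classified from the eigenvalues of the analytic linearization.
#'
#' @param lambda regularization weight (> 0).
#' @param r2 squared ring radius.
#' @param alpha rule magnitude used in the linearization (the stability
#'   classes do not depend on it).
#' @return data frame with columns `dz`, `theta`, `stability`; row names
#'   label the points.
#' @export
find_fixed_points <- function(lambda, r2, alpha = 1) {
  stopifnot(lambda > 0, r2 > 0)
  r <- sqrt(r2)
  pts <- rbind(origin = c(0, 0),
               "ring+" = c(r / sqrt(2), r / sqrt(2)),
               "ring-" = c(-r / sqrt(2), -r / sqrt(2)))
  if (lambda > 1 / r2) {
    q <- sqrt((r2 - 1 / lambda) / 2)
    pts <- rbind(pts, "anti+" = c(q, -q), "anti-" = c(-q, q))
  }
  stability <- apply(pts, 1, function(p) {
    ev <- Re(eigen(reduced_jacobian(p, alpha, lambda, r2),
                   only.values = TRUE)$values)
    if (all(ev < 0)) "stable" else "unstable"
  })
  data.frame(dz = pts[, 1], theta = pts[, 2], stability = stability)
}

#' Predicted adaptation pathway in the weak-regularization limit
#'
#' The sign of the line-attractor endpoint, hence the pathway, is set by the
#' product `alpha1 * alpha2`: above 1 the representational module adapts,
#' below 1 the relational module does. Products within `band` of 1 are
#' labelled `"boundary"` (the separatrix is numerically ill-conditioned).
#'
#' @param alpha1,alpha2 positive rule magnitudes (vectorized).
#' @param band half-width of the boundary band on `alpha1 * alpha2`.
#' @return character vector of labels.
#' @export
predict_pathway <- function(alpha1, alpha2, band = 0.02) {
  stopifnot(all(alpha1 > 0), all(alpha2 > 0))
  p <- alpha1 * alpha2
  ifelse(abs(p - 1) < band, "boundary",
         ifelse(p > 1, "representational", "relational"))
}

# Integrate one post-switch cell of the (alpha1, alpha2) plane and label the
# terminal fixed point: theta > 0 kept its sign (representational), theta < 0
# flipped (relational).
map_cell <- function(alpha1, alpha2, lambda, r2, t_max = 1e4) {
  r <- sqrt(r2)
  start <- c(-(r / sqrt(2)) * (alpha2 / alpha1), r / sqrt(2))
  tr <- reduced_integrate(start, alpha = alpha2, lambda = lambda, r2 = r2,
                          t_max = t_max, n_save = 60L)
  if (!tr$converged && abs(tr$terminal[2]) < 1e-4) return("unresolved")
  if (tr$terminal[2] > 0) "representational" else "relational"
}

#' Pathway map of the reduced model over the (alpha1, alpha2) plane
#'
#' For every grid cell the model is integrated from the post-switch state
#' `(-(r/sqrt(2)) * alpha2 / alpha1, r/sqrt(2))` under rule `alpha2`, and the
#' cell is labelled by the attractor reached: the positive solution keeps the
#' sign of `theta` (representational adaptation), the negative one flips it
#' (relational adaptation).
#'
#' @param alpha1s,alpha2s positive rule grids.
#' @param lambda regularization weight.
#' @param r2 squared ring radius.
#' @return data frame of class `pathway_map` with `alpha1`, `alpha2`, `label`.
#' @export
pathway_map <- function(alpha1s, alpha2s, lambda = 0.1, r2 = 0.1) {
  grid <- expand.grid(alpha1 = alpha1s, alpha2 = alpha2s)
  grid$label <- mapply(map_cell, grid$alpha1, grid$alpha2,
                       MoreArgs = list(lambda = lambda, r2 = r2))
  class(grid) <- c("pathway_map", "data.frame")
  grid
}

#' @export
plot.pathway_map <- function(x, ...) {
  cols <- c(relational = "steelblue", representational = "firebrick",
            unresolved = "gray70")
  graphics::plot(x$alpha1, x$alpha2, col = cols[x$label], pch = 15, log = "xy",
                 xlab = expression(alpha[1]), ylab = expression(alpha[2]), ...)
  a <- exp(seq(log(min(x$alpha1)), log(max(x$alpha1)), length.out = 100))
  graphics::lines(a, 1 / a, lwd = 2)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 15,
                   bty = "n")
  invisible(x)
}

#' Locate the pathway boundary and fit alpha2 = k / alpha1
#'
#' For each `alpha1` the boundary `alpha2` where the integrated label flips
#' is found by bisection; the hyperbola coefficient is estimated as the
#' geometric mean of the products `alpha1 * alpha2*`.
#'
#' @param alpha1s grid of first-phase rules.
#' @param lambda,r2 reduced-model parameters.
#' @param lo,hi bisection bracket on `alpha2`.
#' @param iter bisection iterations.
#' @return list with `boundary` (data frame `alpha1`, `alpha2_star`,
#'   `product`) and `k` (fitted coefficient).
#' @export
fit_boundary <- function(alpha1s, lambda = 0.1, r2 = 0.1,
                         lo = 0.25, hi = 4, iter = 25L) {
  is_rep <- function(a1, a2) {
    map_cell(a1, a2, lambda, r2) == "representational"
  }
  a2_star <- vapply(alpha1s, function(a1) {
    l <- lo; h <- hi
    if (is_rep(a1, l)) return(NA_real_)  # boundary below bracket
    if (!is_rep(a1, h)) return(NA_real_) # boundary above bracket
    for (i in seq_len(iter)) {
      m <- sqrt(l * h)
      if (is_rep(a1, m)) h <- m else l <- m
    }
    sqrt(l * h)
  }, numeric(1))
  boundary <- data.frame(alpha1 = alpha1s, alpha2_star = a2_star,
                         product = alpha1s * a2_star)
  list(boundary = boundary, k = exp(mean(log(boundary$product), na.rm = TRUE)))
}

#' Phase portrait of the reduced model
#'
#' Draws the vector field, the two nullclines, the fixed points and
#' (optionally) trajectories, in the `(delta_z, theta)` plane.
#'
#' @param alpha rule magnitude.
#' @param lambda,r2 reduced-model parameters.
#' @param lim half-width of the plotted square.
#' @param trajectories list of `reduced_trajectory` objects to overlay.
#' @param n_grid arrows per axis.
#' @return invisibly, `NULL`. Draws on the current device.
#' @export
phase_portrait <- function(alpha, lambda = 0.1, r2 = 0.1, lim = NULL,
                           trajectories = list(), n_grid = 17L) {
  r <- sqrt(r2)
  if (is.null(lim)) lim <- 2 * r
  g <- seq(-lim, lim, length.out = n_grid)
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim),
                 xlab = expression(Delta * Z), ylab = expression(theta),
                 main = bquote(alpha == .(alpha)))
  for (dz in g) for (th in g) {
    v <- reduced_flow(c(dz, th), alpha, lambda, r2)
    nv <- sqrt(sum(v^2))
    if (nv > 0) {
      v <- v / nv * lim / n_grid * 0.8
      graphics::arrows(dz, th, dz + v[1], th + v[2], length = 0.03,
                       col = "gray60")
    }
  }
  # nullclines as zero contours of each flow component
  fine <- seq(-lim, lim, length.out = 201)
  fdz <- outer(fine, fine, function(a, b)
    (b - a) - 2 * lambda * (a^2 + b^2 - r2) * a)
  fth <- outer(fine, fine, function(a, b)
    (a - b) - 2 * lambda * (a^2 + b^2 - r2) * b)
  graphics::contour(fine, fine, fdz, levels = 0, add = TRUE,
                    col = "steelblue", drawlabels = FALSE, lwd = 2)
  graphics::contour(fine, fine, fth, levels = 0, add = TRUE,
                    col = "firebrick", drawlabels = FALSE, lwd = 2)
  fps <- find_fixed_points(lambda, r2, alpha)
  graphics::points(fps$dz, fps$theta,
                   pch = ifelse(fps$stability == "stable", 19, 21),
                   cex = 1.4, bg = "white")
  for (tr in trajectories) {
    graphics::lines(tr$states[, "dz"], tr$states[, "theta"],
                    col = "darkorange", lwd = 2)
    graphics::points(tr$states[1, 1], tr$states[1, 2], pch = 17,
                     col = "darkorange")
  }
  invisible(NULL)
}
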