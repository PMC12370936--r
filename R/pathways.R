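# Sign with a numerical dead zone: values closer to zero than `eps` have no
# reliable sign and are treated as "sign not kept" by the classifier.
signed <- function(x, eps = 1e-6) ifelse(abs(x) < eps, 0, sign(x))

#' Classify the adaptation pathway of a trajectory
#'
#' After a rule reversal the representation difference flips sign
#' immediately, violating the expectation held by `theta`. The violation is
#' resolved either by the relational module (`theta` flips to match the
#' post-reversal `delta_z`) or by the representational module (the encoder
#' re-learns so that `delta_z` flips back while `theta` is unchanged). The
#' comparison points are the end of the first phase and the end of the final
#' phase; the sign reference for `delta_z` is the end-of-phase-1 state probed
#' under the final rule (immediately after the switch), so "kept" means the
#' probe sign at the end of training equals the post-switch sign. Agents
#' whose `theta` and `delta_z` both kept or both changed sign necessarily
#' fail the task and are labelled `excluded`.
#'
#' @param traj a [run_protocol()] trajectory spanning at least two phases.
#' @param eps dead-zone half-width: probe values with `|x| < eps` are treated
#'   as having no sign ("kept sign" is false) and flagged in the result.
#' @return an object of class `pathway_outcome`: list with `label` (one of
#'   `"relational"`, `"representational"`, `"excluded"`), `theta_before`,
#'   `theta_after`, `dz_before`, `dz_after`, `dead_zone` (were any probes in
#'   the dead zone) and `flagged` (failed phase-1 learning).
#' @export
classify_pathway <- function(traj, eps = 1e-6) {
  stopifnot(inherits(traj, "pathway_trajectory"),
            length(traj$phase_alphas) >= 2)
  ck <- traj$checkpoints
  boundary <- traj$phase_boundaries[1]
  ck1 <- ck[ck$phase == 1L, ]
  theta_before <- utils::tail(ck1$theta, 1)
  dz_before <- traj$final_rule_ref$mean_dz
  last <- ck[nrow(ck), ]
  theta_after <- last$theta
  dz_after <- last$mean_dz

  s <- c(tb = signed(theta_before, eps), ta = signed(theta_after, eps),
         db = signed(dz_before, eps), da = signed(dz_after, eps))
  theta_kept <- s["tb"] != 0 && s["ta"] != 0 && s["tb"] == s["ta"]
  dz_kept <- s["db"] != 0 && s["da"] != 0 && s["db"] == s["da"]
  label <- if (!theta_kept && dz_kept) "relational"
           else if (theta_kept && !dz_kept) "representational"
           else "excluded"
  structure(list(label = label,
                 theta_before = theta_before, theta_after = theta_after,
                 dz_before = dz_before, dz_after = dz_after,
                 dead_zone = any(s == 0), flagged = isTRUE(traj$flagged)),
            class = "pathway_outcome")
}

#' @export
print.pathway_outcome <- function(x, ...) {
  cat(sprintf("%s adaptation (theta %+0.4f -> %+0.4f, dz %+0.4f -> %+0.4f)%s\n",
              x$label, x$theta_before, x$theta_after, x$dz_before, x$dz_after,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Fraction of agents that adapted their relational module
#'
#' Computed as `#theta / (#Z + #theta)` where `#theta` counts relational and
#' `#Z` representational outcomes; excluded outcomes are removed from both
#' numerator and denominator.
#'
#' @param outcomes list of [classify_pathway()] results (or a character
#'   vector of labels).
#' @return fraction in `[0, 1]`.
#' @export
relational_fraction <- function(outcomes) {
  labels <- if (is.character(outcomes)) outcomes
            else vapply(outcomes, function(o) o$label, character(1))
  n_rel <- sum(labels == "relational")
  n_rep <- sum(labels == "representational")
  if (n_rel + n_rep == 0L)
    stop("all outcomes are excluded: empty cell, no fraction defined")
  n_rel / (n_rel + n_rep)
}

#' Binomial 95% confidence interval for a per-cell fraction
#'
#' Clopper-Pearson interval for `k` relational adapters out of `n`
#' classified agents.
#'
#' @param k successes, @param n trials.
#' @return numeric vector `c(lower, upper)`.
#' @export
fraction_ci <- function(k, n) {
  as.numeric(stats::binom.test(k, n)$conf.int)
}

#' Fit the inflection point of the relational-adaptation curve
#'
#' Fits the two parameters `c` and `d` of the logistic function
#' `1 / (1 + exp(c * (alpha - d)))` to the per-alpha fractions of relational
#' adapters by least squares. When the per-cell agent count `n` is supplied
#' the fit uses binomial variance weights `1 / (p (1 - p) / n)` (with a
#' continuity-corrected `p`), which keeps the confidence interval honest for
#' fraction data whose variance vanishes at the saturated ends of the grid;
#' without `n` the fit is unweighted. The inflection point estimate is `d`;
#' its standard error comes from the fit's parameter covariance and the 95%
#' CI is `1.96 * se_d`.
#'
#' @param alphas grid of rule magnitudes (at least 4 points).
#' @param fractions fraction of relational adapters at each alpha.
#' @param n classified agents per cell (scalar or vector), enabling binomial
#'   weights; `NULL` for unweighted least squares.
#' @param start_c,start_d initial values for the optimizer.
#' @return an object of class `logistic_fit`: list with `c`, `d`, `se_d`,
#'   `ci95_d`, the fitted model and the data.
#' @export
fit_inflection <- function(alphas, fractions, n = NULL, start_c = 10,
                           start_d = stats::median(range(alphas))) {
  stopifnot(length(alphas) == length(fractions), length(alphas) >= 4)
  w <- if (is.null(n)) rep(1, length(alphas)) else {
    stopifnot(all(n > 0))
    ph <- (fractions * n + 0.5) / (n + 1)
    n / (ph * (1 - ph))
  }
  if (all(fractions >= 0.5) || all(fractions <= 0.5)) {
    if (stats::var(fractions) == 0 || min(fractions) > 0.5 || max(fractions) < 0.5)
      stop("fractions show no transition across 0.5; inflection point is not identified")
  }
  df <- data.frame(a = alphas, f = fractions)
  starts <- expand.grid(cc = unique(c(start_c, 5, 20, 50)),
                        d = unique(c(start_d,
                                     stats::quantile(alphas, c(0.25, 0.75)))))
  fit <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(f ~ 1 / (1 + exp(cc * (a - d))), data = df,
                        start = as.list(starts[k, ]), weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients["d", "Std. Error"],
                   error = function(e) Inf)
  } else {
    # direct least squares (robust to perfectly separated step data), with
    # the standard error from the Gauss-Newton covariance at the optimum
    sse <- function(p) {
      sum(w * (df$f - 1 / (1 + exp(p[1] * (df$a - p[2]))))^2)
    }
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      o <- stats::optim(unlist(starts[k, ]), sse, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) stop("logistic fit did not converge")
    est <- c(cc = best$par[[1]], d = best$par[[2]])
    eta <- est["cc"] * (df$a - est["d"])
    mu <- 1 / (1 + exp(eta))
    dmu <- -mu * (1 - mu)                       # d mu / d eta
    J <- sqrt(w) * cbind(cc = dmu * (df$a - est["d"]), d = dmu * -est["cc"])
    dfree <- max(length(df$f) - 2L, 1L)
    sigma2 <- best$value / dfree
    cv <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
    se <- if (is.null(cv)) Inf else sqrt(sigma2 * cv["d", "d"])
  }
  if (!is.finite(se)) se <- Inf
  structure(list(c = unname(est["cc"]), d = unname(est["d"]),
                 se_d = se, ci95_d = 1.96 * se,
                 model = fit, alphas = alphas, fractions = fractions),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit 1/(1 + exp(c (alpha - d)))\n"))
  cat(sprintf("  inflection d = %.4f +/- %.4f (95%% CI), slope c = %.2f\n",
              x$d, x$ci95_d, x$c))
  invisible(x)
}

#' @export
predict.logistic_fit <- function(object, alphas = object$alphas, ...) {
  1 / (1 + exp(object$c * (alphas - object$d)))
}

#' @export
plot.logistic_fit <- function(x, ...) {
  graphics::plot(x$alphas, x$fractions, pch = 19,
                 xlab = expression(alpha), ylab = "fraction relational",
                 ylim = c(0, 1), ...)
  a <- seq(min(x$alphas), max(x$alphas), length.out = 200)
  graphics::lines(a, predict(x, a), col = "forestgreen")
  graphics::abline(v = x$d, lty = 2)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Summarize pathway outcomes over a grid cell
#'
#' @param outcomes list of [classify_pathway()] results.
#' @return one-row data frame with counts, the relational fraction and its
#'   binomial 95% CI (NA when every outcome is excluded).
#' @export
summarize_cell <- function(outcomes) {
  labels <- vapply(outcomes, function(o) o$label, character(1))
  n_rel <- sum(labels == "relational")
  n_rep <- sum(labels == "representational")
  n_exc <- sum(labels == "excluded")
  if (n_rel + n_rep > 0) {
    frac <- n_rel / (n_rel + n_rep)
    ci <- fraction_ci(n_rel, n_rel + n_rep)
  } else {
    frac <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  data.frame(n = length(outcomes), n_relational = n_rel,
             n_representational = n_rep, n_excluded = n_exc,
             fraction = frac, ci_lower = ci[1], ci_upper = ci[2],
             n_flagged = sum(vapply(outcomes, function(o) o$flagged, logical(1))))
}
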