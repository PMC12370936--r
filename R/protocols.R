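#' Train an agent on one task phase
#'
#' Consumes the phase's training pairs in order, in batches of
#' `hyper$batch_pairs` pairs with `hyper$steps_per_batch` SGD steps per batch
#' on the ring-regularized loss. Probes (accuracy and mean `delta_z` over the
#' phase's held-out test set) are recorded every `checkpoint_every` batches
#' and after the final batch.
#'
#' @param agent a [dual_agent()].
#' @param phase an [make_phase()] result rendered at the agent's image side.
#' @param hyper a [dual_hyper()].
#' @param checkpoint_every probe cadence in batches; 0 disables checkpoints.
#' @return list with the updated `agent` and `checkpoints`, a data frame with
#'   columns `pairs_seen`, `theta`, `mean_dz`, `accuracy`, `train_loss`.
#' @export
train_phase <- function(agent, phase, hyper = dual_hyper(),
                        checkpoint_every = 1L) {
  stopifnot(inherits(agent, "dual_agent"), inherits(phase, "order_phase"))
  n <- length(phase$train)
  if (n == 0L) {
    return(list(agent = agent,
                checkpoints = data.frame(pairs_seen = numeric(0),
                                         theta = numeric(0),
                                         mean_dz = numeric(0),
                                         accuracy = numeric(0),
                                         train_loss = numeric(0))))
  }
  stopifnot(nrow(phase$train[[1]]$left_image) == agent$side)
  arr <- pair_arrays(phase$train)
  parr <- pair_arrays(phase$test)
  res <- cpp_train_phase(agent$par, agent$side,
                         as.numeric(arr$left), as.numeric(arr$right), n,
                         hyper$lr, hyper$lambda, hyper$r2,
                         hyper$batch_pairs, hyper$steps_per_batch,
                         as.numeric(parr$left), as.numeric(parr$right),
                         length(phase$test), as.integer(checkpoint_every))
  agent$par <- res$par
  list(agent = agent, checkpoints = as.data.frame(res$checkpoints))
}

# Probe an agent on a freshly drawn 32-pair test set under `alpha`.
probe_under_rule <- function(agent, predictive, alpha, seed, hyper,
                             n_pairs = 32L) {
  cfg <- task_config(predictive, alpha = alpha, n_train_pairs = 0L,
                     n_test_pairs = n_pairs, image_side = agent$side,
                     seed = seed)
  ph <- make_phase(cfg)
  ev <- evaluate_agent(agent, ph$test, hyper)
  list(theta = agent_theta(agent), mean_dz = ev$mean_dz,
       accuracy = ev$accuracy)
}

#' Run a multi-phase training protocol for one agent
#'
#' Trains a freshly initialized agent through a sequence of rules (one phase
#' of `n_pairs` training pairs per rule). Probes use 32 test pairs drawn from
#' the current phase's rule. At the end of the first phase the state is
#' additionally probed under the final phase's rule; that probe is the sign
#' reference against which adaptation-pathway classification compares the
#' final state (see [classify_pathway()]).
#'
#' @param alphas numeric vector of signed rules, one per phase (e.g.
#'   `c(0.5, -0.5)` for a symmetric reversal).
#' @param agent_seed seed for agent initialization.
#' @param stim_seed seed for the stimulus streams (each phase uses its own
#'   offset of this seed).
#' @param predictive predictive feature.
#' @param n_pairs training pairs per phase.
#' @param side image side in pixels.
#' @param hyper a [dual_hyper()].
#' @param checkpoint_every probe cadence in batches.
#' @param fail_threshold phase-1 final accuracy below this flags the agent as
#'   a failed learner (reported, not dropped).
#' @param keep_agent retain the trained agent in the result.
#' @return an object of class `pathway_trajectory`: list with `checkpoints`
#'   (data frame with `phase`, `pairs_seen` cumulative across phases, `theta`,
#'   `mean_dz`, `accuracy`, `train_loss`), `phase_alphas`, `phase_boundaries`
#'   (cumulative pairs at each rule switch), `phase_entry` (state probes at
#'   entry into each phase, under that phase's rule), `final_rule_ref` (the
#'   end-of-phase-1 state probed under the final rule), `flagged`, and seeds.
#' @export
run_protocol <- function(alphas, agent_seed, stim_seed,
                         predictive = "size", n_pairs = 160L, side = 224L,
                         hyper = dual_hyper(), checkpoint_every = 1L,
                         fail_threshold = 0.75, keep_agent = FALSE) {
  stopifnot(length(alphas) >= 1)
  agent <- dual_agent(seed = agent_seed, side = side)
  n_phase <- length(alphas)
  final_alpha <- alphas[n_phase]
  checkpoints <- NULL
  entry <- NULL
  final_rule_ref <- NULL
  phase1_acc <- NA_real_
  offset <- 0L
  for (j in seq_len(n_phase)) {
    cfg <- task_config(predictive, alpha = alphas[j], n_train_pairs = n_pairs,
                       n_test_pairs = 32L, image_side = side,
                       seed = stim_seed + 101L * j)
    ph <- make_phase(cfg)
    pe <- evaluate_agent(agent, ph$test, hyper)
    entry <- rbind(entry, data.frame(phase = j, pairs_seen = offset,
                                     theta = agent_theta(agent),
                                     mean_dz = pe$mean_dz,
                                     accuracy = pe$accuracy))
    res <- train_phase(agent, ph, hyper, checkpoint_every)
    agent <- res$agent
    ck <- res$checkpoints
    if (nrow(ck)) {
      ck$pairs_seen <- ck$pairs_seen + offset
      ck <- cbind(phase = j, ck)
      checkpoints <- rbind(checkpoints, ck)
    }
    if (j == 1L) {
      phase1_acc <- if (nrow(ck)) utils::tail(ck$accuracy, 1) else
        evaluate_agent(agent, ph$test, hyper)$accuracy
      final_rule_ref <- probe_under_rule(agent, predictive, final_alpha,
                                         seed = stim_seed + 104729L, hyper)
    }
    offset <- offset + length(ph$train)
  }
  structure(
    list(checkpoints = checkpoints,
         phase_alphas = alphas,
         phase_boundaries = cumsum(rep(n_pairs, n_phase))[-n_phase],
         phase_entry = entry,
         final_rule_ref = final_rule_ref,
         flagged = is.na(phase1_acc) || phase1_acc < fail_threshold,
         agent_seed = agent_seed, stim_seed = stim_seed,
         predictive = predictive, side = side,
         agent = if (keep_agent) agent else NULL),
    class = "pathway_trajectory")
}

#' @export
print.pathway_trajectory <- function(x, ...) {
  cat(sprintf("Pathway trajectory: rules %s, %d checkpoints%s\n",
              paste(sprintf("%+g", x$phase_alphas), collapse = " -> "),
              nrow(x$checkpoints),
              if (x$flagged) " [flagged: failed phase-1 learning]" else ""))
  ck <- x$checkpoints
  last <- ck[nrow(ck), ]
  cat(sprintf("  final: theta = %+.4f, probe mean dz = %+.4f, accuracy = %.3f\n",
              last$theta, last$mean_dz, last$accuracy))
  invisible(x)
}

#' Plot the evolution of theta and the probe mean representation difference
#'
#' @param x a `pathway_trajectory`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pathway_trajectory <- function(x, ...) {
  ck <- x$checkpoints
  ylim <- range(c(ck$theta, ck$mean_dz), na.rm = TRUE)
  graphics::plot(ck$pairs_seen, ck$mean_dz, type = "l", col = "firebrick",
                 xlab = "image pairs seen", ylab = expression(Delta * Z ~ "," ~ theta),
                 ylim = ylim, ...)
  graphics::lines(ck$pairs_seen, ck$theta, col = "steelblue")
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = x$phase_boundaries, lty = 2, col = "gray50")
  graphics::legend("topright", legend = c(expression(Delta * Z), expression(theta)),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Rule-reversal experiment
#'
#' Each agent trains on `n_pairs` pairs at rule `+alpha1`, then on `n_pairs`
#' pairs at rule `-alpha2`. Agent `i` uses `base_seed + i` for its
#' initialization and an independent stream for its stimuli.
#'
#' @param alpha1,alpha2 positive rule magnitudes before and after reversal.
#' @param n_agents number of independently initialized agents.
#' @param base_seed base of the seed ledger.
#' @inheritParams run_protocol
#' @return list of `pathway_trajectory`, one per agent.
#' @export
run_reversal <- function(alpha1, alpha2, n_agents = 1L, base_seed = 1L,
                         predictive = "size", n_pairs = 160L, side = 224L,
                         hyper = dual_hyper(), checkpoint_every = 1L) {
  stopifnot(alpha1 > 0, alpha2 >= 0)
  lapply(seq_len(n_agents), function(i) {
    run_protocol(c(alpha1, -alpha2),
                 agent_seed = base_seed + i,
                 stim_seed = base_seed + 7919L * i,
                 predictive = predictive, n_pairs = n_pairs, side = side,
                 hyper = hyper, checkpoint_every = checkpoint_every)
  })
}

#' Reversal with an intermediate rule (alpha -> beta -> -alpha)
#'
#' Three phases of `n_pairs` pairs each; the intermediate rule `beta` may be
#' of either sign. Pathway classification compares the end-of-phase-1 state
#' (pair `n_pairs`) with the final state (pair `3 * n_pairs`).
#'
#' @param alpha positive rule magnitude of the first and (negated) final phase.
#' @param beta signed intermediate rule.
#' @inheritParams run_reversal
#' @return list of `pathway_trajectory`, one per agent.
#' @export
run_intermediate <- function(alpha, beta, n_agents = 1L, base_seed = 1L,
                             predictive = "size", n_pairs = 160L, side = 224L,
                             hyper = dual_hyper(), checkpoint_every = 1L) {
  stopifnot(alpha > 0)
  lapply(seq_len(n_agents), function(i) {
    run_protocol(c(alpha, beta, -alpha),
                 agent_seed = base_seed + i,
                 stim_seed = base_seed + 7919L * i,
                 predictive = predictive, n_pairs = n_pairs, side = side,
                 hyper = hyper, checkpoint_every = checkpoint_every)
  })
}
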