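# Reproduction harness: canned experiment presets, a seed ledger and a run
# manifest, so every emitted artifact is reachable from one manifest and
# every stochastic stage is reproducible from its recorded seeds.

figure_presets <- function(figure, scale) {
  full <- list(
    fig2  = list(n_agents = 100L, alpha = 0.5),
    fig4  = list(n_agents = 100L, alphas = c(0.2, 0.8)),
    fig5a = list(n_agents = 100L,
                 alphas = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)),
    fig5b = list(n_agents = 50L, alpha1s = seq(0.2, 1, by = 0.2),
                 alpha2s = seq(0.2, 1, by = 0.2)),
    fig6  = list(n_agents = 50L, alphas = seq(0.1, 0.9, by = 0.2),
                 betas = c(-0.8, -0.4, -0.1, 0.1, 0.4, 0.8)),
    fig7  = list(alphas = c(2, 0.5)),
    fig8  = list(n_grid = 13L))
  desk <- utils::modifyList(full, list(
    fig2  = list(n_agents = 5L, alpha = 0.5),
    fig4  = list(n_agents = 3L, alphas = c(0.2, 0.8)),
    fig5a = list(n_agents = 20L,
                 alphas = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.7, 1.0)),
    fig5b = list(n_agents = 10L, alpha1s = c(0.2, 0.5, 0.8, 1.0),
                 alpha2s = c(0.2, 0.5, 0.8, 1.0)),
    fig6  = list(n_agents = 10L, alphas = c(0.2, 0.35, 0.5, 0.8),
                 betas = c(-0.8, -0.1, 0.1, 0.8)),
    fig7  = list(alphas = c(2, 0.5)),
    fig8  = list(n_grid = 9L)))
  presets <- if (scale == "full") full else desk
  presets[[figure]]
}

traj_to_df <- function(trajs, ids = seq_along(trajs)) {
  do.call(rbind, lapply(seq_along(trajs), function(i) {
    ck <- trajs[[i]]$checkpoints
    cbind(agent = ids[i], ck)
  }))
}

#' Reproduce one of the study's figures
#'
#' Runs the corresponding experiment at `"full"` scale (100 or 50 agents per
#' cell) or the much cheaper `"desk"` scale, and writes the figure (PNG), the
#' underlying tidy CSV (one row per agent per checkpoint, or per grid cell)
#' and a JSON run manifest into `out_dir`. The ANN figures (fig2, fig4,
#' fig5a, fig5b, fig6) train convolutional agents and take minutes to hours
#' depending on scale; fig7 and fig8 use the reduced scalar model and run in
#' seconds to a minute.
#'
#' @param figure one of `"fig2"` (learning curve and solution trajectories),
#'   `"fig4"` (symmetric reversal), `"fig5a"` (relational fraction vs alpha
#'   with logistic fit), `"fig5b"` (general alpha1 -> -alpha2 grid), `"fig6"`
#'   (intermediate-step shaping), `"fig7"` (reduced-model phase portraits),
#'   `"fig8"` (reduced-model pathway map and boundary).
#' @param scale `"desk"` or `"full"`.
#' @param out_dir output directory.
#' @param base_seed base of the seed ledger.
#' @param side image side for ANN experiments.
#' @param overrides named list overriding preset fields (e.g. `n_agents`).
#' @return invisibly, the manifest list.
#' @export
reproduce_figure <- function(figure = c("fig2", "fig4", "fig5a", "fig5b",
                                        "fig6", "fig7", "fig8"),
                             scale = c("desk", "full"),
                             out_dir = file.path("reproduction", figure),
                             base_seed = 1L, side = 224L,
                             overrides = list()) {
  figure <- match.arg(figure)
  scale <- match.arg(scale)
  preset <- utils::modifyList(figure_presets(figure, scale), overrides)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hyper <- dual_hyper()
  files <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  emit_png <- function(name, expr, width = 900, height = 450) {
    path <- file.path(out_dir, name)
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    files <<- c(files, path)
    path
  }
  summary <- list()

  if (figure == "fig2") {
    trajs <- lapply(seq_len(preset$n_agents), function(i) {
      run_protocol(preset$alpha, agent_seed = base_seed + i,
                   stim_seed = base_seed + 7919L * i, side = side,
                   hyper = hyper, checkpoint_every = 1L)
    })
    df <- traj_to_df(trajs)
    emit_csv(df, "trajectories.csv")
    mean_acc <- stats::aggregate(accuracy ~ pairs_seen, df, mean)
    emit_png("learning_curve.png", {
      graphics::par(mfrow = c(1, 2))
      graphics::plot(mean_acc$pairs_seen, mean_acc$accuracy, type = "l",
                     xlab = "training pairs", ylab = "mean test accuracy",
                     ylim = c(0, 1))
      graphics::abline(h = 0.9, lty = 3)
      plot(trajs[[1]], main = "example solution")
    })
    summary <- list(final_mean_accuracy = mean_acc$accuracy[nrow(mean_acc)],
                    pairs_to_0.9 = mean_acc$pairs_seen[
                      which(mean_acc$accuracy > 0.9)[1]])
  } else if (figure == "fig4") {
    rows <- list()
    for (a in preset$alphas) {
      trajs <- run_reversal(a, a, n_agents = preset$n_agents,
                            base_seed = base_seed, side = side, hyper = hyper)
      df <- traj_to_df(trajs)
      df$alpha <- a
      rows[[length(rows) + 1L]] <- df
    }
    df <- do.call(rbind, rows)
    emit_csv(df, "reversal_trajectories.csv")
    emit_png("reversal.png", {
      graphics::par(mfrow = c(1, length(preset$alphas)))
      for (a in preset$alphas) {
        sub <- df[df$alpha == a & df$agent == 1L, ]
        graphics::plot(sub$pairs_seen, sub$mean_dz, type = "l",
                       col = "firebrick", ylim = range(c(sub$mean_dz, sub$theta)),
                       xlab = "pairs", ylab = "dz, theta",
                       main = sprintf("alpha = %g", a))
        graphics::lines(sub$pairs_seen, sub$theta, col = "steelblue")
        graphics::abline(v = 160, lty = 2); graphics::abline(h = 0, lty = 3)
      }
    })
  } else if (figure == "fig5a") {
    cells <- lapply(preset$alphas, function(a) {
      trajs <- run_reversal(a, a, n_agents = preset$n_agents,
                            base_seed = base_seed + round(1000 * a),
                            side = side, hyper = hyper, checkpoint_every = 5L)
      outcomes <- lapply(trajs, classify_pathway)
      cbind(alpha = a, summarize_cell(outcomes))
    })
    df <- do.call(rbind, cells)
    emit_csv(df, "fractions.csv")
    fit <- fit_inflection(df$alpha, df$fraction,
                          n = df$n_relational + df$n_representational)
    emit_png("fraction_vs_alpha.png", plot(fit), width = 500, height = 450)
    fit_report <- list(c = fit$c, d = fit$d, se_d = fit$se_d,
                       ci95_d = fit$ci95_d)
    jsonlite::write_json(fit_report, file.path(out_dir, "logistic_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out_dir, "logistic_fit.json"))
    summary <- fit_report
  } else if (figure == "fig5b") {
    grid <- expand.grid(alpha1 = preset$alpha1s, alpha2 = preset$alpha2s)
    cells <- lapply(seq_len(nrow(grid)), function(g) {
      trajs <- run_reversal(grid$alpha1[g], grid$alpha2[g],
                            n_agents = preset$n_agents,
                            base_seed = base_seed + 97L * g, side = side,
                            hyper = hyper, checkpoint_every = 5L)
      outcomes <- lapply(trajs, classify_pathway)
      cbind(grid[g, ], summarize_cell(outcomes))
    })
    df <- do.call(rbind, cells)
    emit_csv(df, "grid_fractions.csv")
    emit_png("grid.png", {
      graphics::plot(df$alpha1, df$alpha2,
                     pch = ifelse(df$fraction >= 0.5, 24, 22),
                     bg = grDevices::gray(1 - df$fraction),
                     xlab = "alpha1", ylab = "alpha2", cex = 2)
    }, width = 500, height = 450)
  } else if (figure == "fig6") {
    rows <- list()
    for (b in preset$betas) {
      cells <- lapply(preset$alphas, function(a) {
        trajs <- run_intermediate(a, b, n_agents = preset$n_agents,
                                  base_seed = base_seed +
                                    round(1000 * a) + round(10000 * abs(b)) +
                                    (b < 0) * 3L,
                                  side = side, hyper = hyper,
                                  checkpoint_every = 5L)
        outcomes <- lapply(trajs, classify_pathway)
        cbind(alpha = a, beta = b, summarize_cell(outcomes))
      })
      rows[[length(rows) + 1L]] <- do.call(rbind, cells)
    }
    df <- do.call(rbind, rows)
    emit_csv(df, "shaping_fractions.csv")
    abar <- vapply(preset$betas, function(b) {
      sub <- df[df$beta == b, ]
      tryCatch(fit_inflection(sub$alpha, sub$fraction,
                              n = sub$n_relational + sub$n_representational)$d,
               error = function(e) NA_real_)
    }, numeric(1))
    out <- data.frame(beta = preset$betas, alpha_bar = abar)
    emit_csv(out, "alpha_bar_vs_beta.csv")
    emit_png("shaping.png", {
      graphics::plot(out$beta, out$alpha_bar, pch = 19, xlab = "beta",
                     ylab = "fitted inflection alpha-bar")
    }, width = 500, height = 450)
    summary <- list(alpha_bar = stats::setNames(abar, preset$betas))
  } else if (figure == "fig7") {
    r2 <- 0.1; lambda <- 0.1; r <- sqrt(r2)
    start <- c(-r / sqrt(2), r / sqrt(2))
    trs <- lapply(preset$alphas, function(a)
      reduced_integrate(start, a, lambda, r2))
    emit_png("phase_portraits.png", {
      graphics::par(mfrow = c(1, length(preset$alphas)))
      for (i in seq_along(preset$alphas))
        phase_portrait(preset$alphas[i], lambda, r2,
                       trajectories = trs[i])
    })
    df <- do.call(rbind, lapply(seq_along(trs), function(i) {
      data.frame(alpha = preset$alphas[i], t = trs[[i]]$times,
                 dz = trs[[i]]$states[, "dz"],
                 theta = trs[[i]]$states[, "theta"])
    }))
    emit_csv(df, "trajectories.csv")
    summary <- list(terminal_theta = vapply(trs, function(tr)
      unname(tr$terminal[2]), numeric(1)))
  } else if (figure == "fig8") {
    g <- exp(seq(log(0.25), log(4), length.out = preset$n_grid))
    map <- pathway_map(g, g, lambda = 0.1, r2 = 0.1)
    emit_csv(map, "pathway_map.csv")
    bd <- fit_boundary(g, lambda = 0.1, r2 = 0.1)
    emit_csv(bd$boundary, "boundary.csv")
    emit_png("pathway_map.png", plot(map), width = 500, height = 450)
    summary <- list(boundary_product_k = bd$k)
  }

  manifest <- list(
    figure = figure, scale = scale, preset = preset, base_seed = base_seed,
    side = side,
    hyper = unclass(hyper),
    package_version = as.character(utils::packageVersion("dualpath")),
    files = basename(files),
    summary = summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
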