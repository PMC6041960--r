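## End-to-end experiment: lexicon -> n trained simulations -> lesion battery
## -> condition summaries -> interaction analysis.

#' Run the full simulation experiment
#'
#' Generates the lexicon, trains `n_simulations` networks from different
#' initial weight matrices, runs the semantic-lesion battery on each, and
#' performs the repeated-measures lesion x condition analysis. Fully
#' deterministic given `config$seed`.
#'
#' @param config A `knet_config` from [default_config()] or
#'   [validate_config()].
#' @param out_dir Optional directory; when given, the lexicon (TSV + JSON),
#'   per-simulation checkpoints, training logs, battery and summary CSVs and
#'   the ANOVA report are written there.
#' @param keep_fits Return the trained `knet_fit` objects (memory-heavy for
#'   many simulations).
#' @param progress Print per-simulation progress.
#' @return List with `lexicon`, `battery`, `summary`, `anova` (all three
#'   conditions), `anova_2x2` (typical vs atypical, the key interaction),
#'   `surface_anova` (surface-error rate, typical vs atypical), `config`, and
#'   optionally `fits`.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           keep_fits = FALSE, progress = interactive()) {
  stopifnot(inherits(config, "knet_config") || is.list(config))
  lx <- config$lexicon
  lexicon <- generate_lexicon(
    n_chars = lx$n_chars, n_words = lx$n_words,
    n_per_condition = lx$n_per_condition,
    prop_consistent = lx$prop_consistent,
    frequency_params = lx$frequency_params,
    seed = derive_seed(config$seed, "lexicon_master")
  )
  spec <- spec_for_lexicon(lexicon, hidden = unlist(config$network$hidden),
                           n_timesteps = config$network$n_timesteps,
                           integration_rate = config$network$integration_rate,
                           gain = config$network$gain)
  tr <- config$training
  pre <- phase_spec("preliteracy", epochs = tr$preliteracy_epochs,
                    lr_start = tr$lr_start, lr_decrement = tr$lr_decrement,
                    wd_start = tr$wd_start, wd_decrement = tr$wd_decrement)
  lit <- phase_spec("literacy", epochs = tr$literacy_epochs,
                    lr_start = tr$lr_start, lr_decrement = tr$lr_decrement,
                    wd_start = tr$wd_start, wd_decrement = tr$wd_decrement)
  drill <- drill_spec(test_every = tr$drill_test_every,
                      reiterations = tr$drill_reiterations)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_lexicon(lexicon, file.path(out_dir, "lexicon"))
    write_config(config, file.path(out_dir, "config.json"))
  }

  fits <- vector("list", config$n_simulations)
  for (si in seq_len(config$n_simulations)) {
    sim_seed <- derive_seed(config$seed, "simulation", si)
    if (progress) message("simulation ", si, "/", config$n_simulations,
                          " (seed ", sim_seed, ")")
    fit <- train_full(lexicon, spec, seed = sim_seed, preliteracy = pre,
                      literacy = lit, drill = drill,
                      radius = tr$zero_error_radius)
    fits[[si]] <- fit
    if (!is.null(out_dir)) {
      write_checkpoint(fit, file.path(out_dir,
                                      sprintf("checkpoint_sim%02d.rds", si)))
      utils::write.csv(fit$log,
                       file.path(out_dir, sprintf("train_log_sim%02d.csv", si)),
                       row.names = FALSE)
    }
  }

  lcfg <- lesion_config(fraction = config$lesion$fraction,
                        repetitions = config$lesion$repetitions,
                        seed = derive_seed(config$seed, "lesion_master"))
  battery <- run_battery(fits, lexicon, lcfg)
  summ <- summarize_battery(battery)
  anova_all <- interaction_anova(summ)
  inc <- summ[summ$condition %in% c("typical", "atypical"), ]
  anova_2x2 <- interaction_anova(inc)
  surface_anova <- interaction_anova(inc, dv = "surface_rate")

  if (!is.null(out_dir)) {
    utils::write.csv(battery, file.path(out_dir, "battery.csv"),
                     row.names = FALSE)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    rep <- rbind(cbind(analysis = "accuracy_all", anova_all$effects),
                 cbind(analysis = "accuracy_2x2", anova_2x2$effects),
                 cbind(analysis = "surface_2x2", surface_anova$effects))
    utils::write.csv(rep, file.path(out_dir, "anova.csv"), row.names = FALSE)
  }

  out <- list(lexicon = lexicon, battery = battery, summary = summ,
              anova = anova_all, anova_2x2 = anova_2x2,
              surface_anova = surface_anova, config = config)
  if (keep_fits) out$fits <- fits
  out
}

#' Condition-level means across simulations
#'
#' The numbers usually reported: per condition x lesion status, the mean and
#' standard error (over simulations) of accuracy and surface-error rate.
#'
#' @param summ Output of [summarize_battery()].
#' @return Data frame of condition x lesion-status means.
#' @export
condition_means <- function(summ) {
  f <- interaction(summ$condition, summ$lesion_status, drop = TRUE)
  out <- do.call(rbind, lapply(split(summ, f), function(d) {
    data.frame(condition = d$condition[1], lesion_status = d$lesion_status[1],
               n_sim = nrow(d),
               accuracy = mean(d$accuracy),
               accuracy_se = stats::sd(d$accuracy) / sqrt(nrow(d)),
               surface_rate = mean(d$surface_rate),
               semantic_rate = mean(d$semantic_rate),
               other_rate = mean(d$other_rate),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(match(out$condition, c("consistent", "typical", "atypical")),
            out$lesion_status), ]
}
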