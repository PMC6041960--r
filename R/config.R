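## Run configuration: defaults, validation, serialization.

#' Default experiment configuration
#'
#' Two profiles are provided. `"paper"` carries the full-scale settings: 20
#' epochs per phase, learning rate 0.5 decremented by 0.05 (weight decay 5e-7
#' by 5e-8) per 10 preliteracy / 2 literacy epochs, 20 time steps with
#' integration rate 0.1 and gain 1, zero-error radius 0.1, 5% semantic lesion
#' with 50 repetitions, 15 simulations. `"desk"` is the scaled-down profile
#' used by the test suite on one CPU: the same lexicon statistics at 300
#' characters / 1200 words, 6 preliteracy + 10 literacy epochs, asymmetric
#' hidden layers (more capacity on the semantically mediated pathway, where
#' the item-specific mappings live), a learning-rate schedule scaled to one
#' fifth of the full-scale values (0.1 by 0.01; the full-size rate is unstable for
#' online updates at this network scale), 20 lesion repetitions and 5
#' simulations.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param seed Master seed; every stochastic component derives its own seed
#'   from it.
#' @return A nested configuration list (class `knet_config`).
#' @export
default_config <- function(profile = c("desk", "paper"), seed = 1L) {
  profile <- match.arg(profile)
  paper <- profile == "paper"
  cfg <- list(
    profile = profile,
    seed = as.integer(seed),
    lexicon = list(
      n_chars = if (paper) 2000L else 300L,
      n_words = if (paper) 9818L else 1200L,
      n_per_condition = if (paper) 40L else 20L,
      prop_consistent = 1 / 3,
      frequency_params = list(mean_log10 = 1.0, sd_log10 = 0.6,
                              test_log10_target = 0.77,
                              test_log10_window = 0.45)
    ),
    network = list(
      hidden = if (paper) {
        list(vis_sem = 100L, vis_phin = 50L, sem_phout = 150L,
             phin_phout = 50L)
      } else {
        list(vis_sem = 80L, vis_phin = 25L, sem_phout = 120L,
             phin_phout = 25L)
      },
      n_timesteps = 20L,
      integration_rate = 0.1,
      gain = 1.0
    ),
    training = list(
      preliteracy_epochs = if (paper) 20L else 6L,
      literacy_epochs = if (paper) 20L else 10L,
      lr_start = if (paper) 0.5 else 0.1,
      lr_decrement = if (paper) 0.05 else 0.01,
      wd_start = 5e-7,
      wd_decrement = 5e-8,
      zero_error_radius = 0.1,
      drill_test_every = 2L,
      drill_reiterations = 20L
    ),
    lesion = list(
      fraction = 0.05,
      repetitions = if (paper) 50L else 20L
    ),
    n_simulations = if (paper) 15L else 5L
  )
  structure(cfg, class = "knet_config")
}

## allowed keys per section, for validation
config_schema <- function() {
  list(
    top = c("profile", "seed", "lexicon", "network", "training", "lesion",
            "n_simulations"),
    lexicon = c("n_chars", "n_words", "n_per_condition", "prop_consistent",
                "frequency_params"),
    frequency_params = c("mean_log10", "sd_log10", "test_log10_target",
                         "test_log10_window"),
    network = c("hidden", "n_timesteps", "integration_rate", "gain"),
    training = c("preliteracy_epochs", "literacy_epochs", "lr_start",
                 "lr_decrement", "wd_start", "wd_decrement",
                 "zero_error_radius", "drill_test_every",
                 "drill_reiterations"),
    lesion = c("fraction", "repetitions")
  )
}

#' Validate a (possibly partial) configuration
#'
#' Fills every omitted field with its profile default so the effective
#' configuration is fully explicit, and rejects unknown keys and out-of-range
#' values with messages naming the offending field.
#'
#' @param raw A named list (e.g. parsed from JSON), a path to a JSON file, or
#'   NULL for pure defaults.
#' @param profile Profile supplying the defaults (overridden by a `profile`
#'   entry in `raw`).
#' @return A complete `knet_config`.
#' @export
validate_config <- function(raw = NULL, profile = "desk") {
  if (is.character(raw) && length(raw) == 1L) {
    raw <- jsonlite::read_json(raw, simplifyVector = TRUE)
  }
  raw <- raw %||% list()
  if (!is.null(raw$profile)) profile <- raw$profile
  if (!profile %in% c("desk", "paper")) {
    stop("config error: profile must be 'desk' or 'paper'")
  }
  cfg <- default_config(profile, seed = raw$seed %||% 1L)
  sch <- config_schema()
  bad <- setdiff(names(raw), sch$top)
  if (length(bad)) stop("config error: unknown key(s): ",
                        paste(bad, collapse = ", "))
  for (sec in c("lexicon", "network", "training", "lesion")) {
    if (is.null(raw[[sec]])) next
    bad <- setdiff(names(raw[[sec]]), sch[[sec]])
    if (length(bad)) stop("config error: unknown key(s) in ", sec, ": ",
                          paste(bad, collapse = ", "))
    cfg[[sec]] <- utils::modifyList(cfg[[sec]], raw[[sec]])
  }
  if (!is.null(raw$n_simulations)) cfg$n_simulations <- raw$n_simulations

  chk <- function(ok, field, msg) {
    if (!ok) stop("config error: ", field, " ", msg, call. = FALSE)
  }
  chk(cfg$lexicon$n_chars >= 6, "lexicon.n_chars", "must be >= 6")
  chk(cfg$lexicon$n_words >= 1, "lexicon.n_words", "must be positive")
  chk(cfg$lexicon$n_per_condition >= 1, "lexicon.n_per_condition",
      "must be positive")
  chk(cfg$lexicon$prop_consistent > 0 && cfg$lexicon$prop_consistent <= 1,
      "lexicon.prop_consistent", "must be in (0, 1]")
  chk(all(unlist(cfg$network$hidden) >= 1), "network.hidden",
      "must be positive")
  chk(cfg$network$n_timesteps >= 1, "network.n_timesteps", "must be positive")
  chk(cfg$network$integration_rate > 0 && cfg$network$integration_rate <= 1,
      "network.integration_rate", "must be in (0, 1]")
  chk(cfg$training$lr_start >= 0, "training.lr_start", "must be >= 0")
  chk(cfg$training$zero_error_radius >= 0, "training.zero_error_radius",
      "must be >= 0")
  chk(cfg$lesion$fraction >= 0 && cfg$lesion$fraction <= 1, "lesion.fraction",
      "must be in [0, 1]")
  chk(cfg$lesion$repetitions >= 1, "lesion.repetitions", "must be >= 1")
  chk(cfg$n_simulations >= 1, "n_simulations", "must be >= 1")
  cfg
}

#' Write a configuration to JSON
#'
#' @param config A `knet_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
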