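## Semantic-layer lesion battery: random deactivation of semantic units,
## repeated sampling, averaging across independently trained simulations.

#' Lesion configuration
#'
#' @param fraction Fraction of semantic units deactivated per repetition
#'   (default 0.05, i.e. approximately 5%).
#' @param repetitions Independent lesion samples per simulation (default 50).
#' @param seed Integer seed from which every repetition's mask is derived.
#' @return An object of class `knet_lesion_config`.
#' @export
lesion_config <- function(fraction = 0.05, repetitions = 50L, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (repetitions < 1L) stop("repetitions must be >= 1")
  structure(list(fraction = fraction, repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "knet_lesion_config")
}

#' Apply a random semantic lesion
#'
#' Selects `round(fraction * size)` distinct semantic units with the
#' repetition-indexed RNG and clamps their activations to 0 at every time
#' step. Weights are untouched; the mask is reversible via [clear_lesion()].
#'
#' @param net A `knet_network`.
#' @param config A `knet_lesion_config`.
#' @param rep_index Repetition index (each repetition draws its own mask).
#' @return The network with the lesion mask set.
#' @export
apply_lesion <- function(net, config, rep_index = 1L) {
  stopifnot(inherits(config, "knet_lesion_config"))
  size <- net$spec$layers$size[layer_index(net$spec, "semantic")]
  n_off <- round(config$fraction * size)
  units <- if (n_off == 0L) integer(0) else {
    with_seed(derive_seed(config$seed, "lesion", rep_index), {
      sample.int(size, n_off)
    })
  }
  net$lesion <- list(layer = "semantic", units = sort(units))
  net
}

#' Remove any lesion mask
#'
#' @param net A `knet_network`.
#' @return The network with no lesion; outputs are bit-identical to the
#'   never-lesioned model.
#' @export
clear_lesion <- function(net) {
  net["lesion"] <- list(NULL)  # keep the element, set it to NULL
  net
}

#' Run the lesion battery over trained simulations
#'
#' For each trained network: evaluates reading on the lexicon's test set
#' unlesioned (one set of condition rows, `repetition = 0`), then under
#' `config$repetitions` independently sampled semantic lesions. Accuracies and
#' error-class rates are reported per repetition; average within simulation
#' with [summarize_battery()].
#'
#' @param fits List of `knet_fit` (or bare `knet_network`) objects, one per
#'   simulation.
#' @param lexicon The `knet_lexicon` the models were trained on.
#' @param config A `knet_lesion_config`.
#' @return Battery data frame: simulation_seed, repetition, lesion_status,
#'   condition, accuracy and error-class rates.
#' @export
run_battery <- function(fits, lexicon, config = lesion_config()) {
  if (length(fits) < 1L) stop("no trained simulations supplied")
  test_idx <- match(lexicon$test_ids, lexicon$words$word_id)
  if (length(test_idx) == 0L) stop("lexicon has no test set")
  thr <- semantic_null_threshold(lexicon,
                                 seed = derive_seed(config$seed, "null"))
  rows <- list()
  for (si in seq_along(fits)) {
    fit <- fits[[si]]
    net <- if (inherits(fit, "knet_fit")) fit$net else fit
    sim_seed <- if (inherits(fit, "knet_fit")) fit$seed else si
    net <- clear_lesion(net)
    base <- condition_rates(evaluate_reading(net, lexicon, test_idx, thr))
    base$simulation_seed <- sim_seed
    base$repetition <- 0L
    base$lesion_status <- "unlesioned"
    rows[[length(rows) + 1L]] <- base
    for (rep in seq_len(config$repetitions)) {
      lnet <- apply_lesion(net, config,
                           rep_index = si * 100000L + rep)
      r <- condition_rates(evaluate_reading(lnet, lexicon, test_idx, thr))
      r$simulation_seed <- sim_seed
      r$repetition <- rep
      r$lesion_status <- "lesioned"
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
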