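## Developmental training regime: preliteracy, weight freezing, literacy with
## scheduled learning-rate/weight-decay decay and drilling on failed items.

#' Specify a training phase
#'
#' @param name `"preliteracy"` or `"literacy"`.
#' @param epochs Number of epochs.
#' @param presentations Named list mapping task to per-item presentation count
#'   within one epoch. Defaults: preliteracy presents each item 19 times for
#'   speaking and once for repetition (95%/5%); literacy presents each item 6
#'   times for reading (30%), 12 for comprehension (60%), once for speaking
#'   (5%) and once for repetition (5%).
#' @param lr_start,lr_decrement,lr_interval Learning-rate schedule: the rate
#'   starts at `lr_start` and drops by `lr_decrement` each time `lr_interval`
#'   epochs complete (never below 0). Defaults 0.5 / 0.05 per 10 epochs
#'   (preliteracy) or per 2 epochs (literacy).
#' @param wd_start,wd_decrement,wd_interval Weight-decay schedule, analogous;
#'   defaults 5e-7 / 5e-8 on the same intervals.
#' @param frequency_scaling Scale error derivatives by the square root of the
#'   word's occurrences-per-million frequency.
#' @return An object of class `knet_phase`.
#' @export
phase_spec <- function(name = c("preliteracy", "literacy"), epochs = NULL,
                       presentations = NULL, lr_start = 0.5,
                       lr_decrement = 0.05, lr_interval = NULL,
                       wd_start = 5e-7, wd_decrement = 5e-8,
                       wd_interval = NULL, frequency_scaling = TRUE) {
  name <- match.arg(name)
  if (is.null(epochs)) epochs <- 20L
  if (is.null(presentations)) {
    presentations <- if (name == "preliteracy") {
      list(speaking = 19L, repetition = 1L)
    } else {
      list(reading = 6L, comprehension = 12L, speaking = 1L, repetition = 1L)
    }
  }
  if (is.null(lr_interval)) lr_interval <- if (name == "preliteracy") 10L else 2L
  if (is.null(wd_interval)) wd_interval <- lr_interval
  stopifnot(all(names(presentations) %in% names(TASKS)),
            all(unlist(presentations) >= 1L), epochs >= 0L,
            lr_start >= 0, lr_interval >= 1L, wd_interval >= 1L)
  structure(list(name = name, epochs = as.integer(epochs),
                 presentations = presentations, lr_start = lr_start,
                 lr_decrement = lr_decrement,
                 lr_interval = as.integer(lr_interval), wd_start = wd_start,
                 wd_decrement = wd_decrement,
                 wd_interval = as.integer(wd_interval),
                 frequency_scaling = isTRUE(frequency_scaling)),
            class = "knet_phase")
}

#' Specify the drilling regime
#'
#' @param test_every Run a reading test on the test set after every
#'   `test_every` literacy epochs.
#' @param reiterations Extra unscaled reading trials given to each failed item
#'   at each scheduled test.
#' @return An object of class `knet_drill`.
#' @export
drill_spec <- function(test_every = 2L, reiterations = 20L) {
  stopifnot(test_every >= 1L, reiterations >= 0L)
  structure(list(test_every = as.integer(test_every),
                 reiterations = as.integer(reiterations),
                 frequency_scaling = FALSE),
            class = "knet_drill")
}

#' Root-frequency error-derivative multiplier
#'
#' The square root of a word's occurrences-per-million frequency, the raw
#' per-word training emphasis (a frequency of 4 per million gives 2). Inside
#' [run_phase()] these are normalized by the lexicon maximum before scaling
#' the error derivatives.
#'
#' @param frequency Occurrences per million (>= 0).
#' @return `sqrt(frequency)`.
#' @export
root_frequency <- function(frequency) {
  stopifnot(all(frequency >= 0))
  sqrt(frequency)
}

## closed-form schedule value at 0-based epoch e: the first `interval` epochs
## run at `start`; each completed interval knocks off one decrement
schedule_value <- function(start, decrement, interval, epoch0) {
  max(0, start - decrement * (epoch0 %/% interval))
}

#' Run one training phase
#'
#' Each epoch flattens the presentation multiset (every word x every task x
#' its per-item count), shuffles it with an epoch-derived seed, and trains
#' through the shuffled list online. The learning rate and weight decay follow
#' their closed-form schedules; if `drill` is given, a reading test on
#' `test_idx` is run after every `drill$test_every` epochs and failed items
#' receive `drill$reiterations` extra unscaled reading trials each.
#'
#' @param net A `knet_network`.
#' @param lexicon A `knet_lexicon`.
#' @param phase A `knet_phase`.
#' @param seed Integer seed for the per-epoch shuffles.
#' @param radius Zero-error radius.
#' @param drill Optional `knet_drill`.
#' @param test_idx Word row indices of the test set (required with `drill`).
#' @return List with `net`, `log` (one row per epoch x task: trial count, mean
#'   loss, lr, wd) and `drill_log` (one row per scheduled test).
#' @export
run_phase <- function(net, lexicon, phase, seed = 1L, radius = 0.1,
                      drill = NULL, test_idx = NULL) {
  stopifnot(inherits(phase, "knet_phase"))
  if (!is.null(drill) && is.null(test_idx)) {
    stop("drilling requires test_idx")
  }
  n_words <- nrow(lexicon$words)
  ## square-root frequency weighting, normalized by the lexicon maximum so
  ## the largest per-trial step equals the learning rate; relative weighting
  ## between words stays exactly proportional to sqrt(frequency). Online
  ## updates destabilize when single trials take steps above the nominal
  ## rate, so the maximum (not the mean) is the safe normalizer.
  freq_scale_word <- if (phase$frequency_scaling) {
    fs <- root_frequency(lexicon$words$frequency)
    fs / max(fs)
  } else rep(1, n_words)

  log_rows <- list(); drill_rows <- list()
  warned_underflow <- FALSE
  for (e in seq_len(phase$epochs)) {
    lr_raw <- phase$lr_start - phase$lr_decrement * ((e - 1L) %/% phase$lr_interval)
    if (lr_raw < 0 && !warned_underflow) {
      warning("learning-rate schedule underflow; clamped at 0")
      warned_underflow <- TRUE
    }
    lr <- max(0, lr_raw)
    wd <- schedule_value(phase$wd_start, phase$wd_decrement,
                         phase$wd_interval, e - 1L)

    sched <- do.call(rbind, lapply(names(phase$presentations), function(tk) {
      data.frame(word = rep(seq_len(n_words), phase$presentations[[tk]]),
                 task = tk, stringsAsFactors = FALSE)
    }))
    sched <- with_seed(derive_seed(seed, paste0("shuffle_", phase$name), e), {
      sched[sample.int(nrow(sched)), , drop = FALSE]
    })
    res <- train_trials(net, lexicon, sched$word, sched$task, lr = lr,
                        weight_decay = wd,
                        freq_scale = freq_scale_word[sched$word],
                        radius = radius)
    net <- res$net
    for (tk in names(phase$presentations)) {
      sel <- sched$task == tk
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        phase = phase$name, epoch = e, task = tk, n_trials = sum(sel),
        mean_loss = mean(res$loss[sel]), lr = lr, wd = wd,
        stringsAsFactors = FALSE)
    }

    if (!is.null(drill) && e %% drill$test_every == 0L) {
      dres <- run_drilling(net, lexicon, drill, test_idx, lr = lr, wd = wd,
                           radius = radius)
      net <- dres$net
      drill_rows[[length(drill_rows) + 1L]] <- data.frame(
        phase = phase$name, epoch = e, accuracy = dres$accuracy,
        n_failed = dres$n_failed, n_drill_trials = dres$n_trials)
    }
  }
  list(net = net,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(),
       drill_log = if (length(drill_rows)) do.call(rbind, drill_rows) else
         data.frame())
}

#' Run one drilling pass
#'
#' Tests reading on the test set with the full nearest-neighbor decode; every
#' incorrect item then receives `drill$reiterations` additional reading
#' trials whose error derivatives are *not* frequency-scaled.
#'
#' @param net A `knet_network`.
#' @param lexicon A `knet_lexicon`.
#' @param drill A `knet_drill`.
#' @param test_idx Word row indices of the test set.
#' @param lr,wd Current learning rate and weight decay.
#' @param radius Zero-error radius.
#' @return List with `net`, pre-drill `accuracy`, `n_failed`, `n_trials` and
#'   the drilled word indices.
#' @export
run_drilling <- function(net, lexicon, drill, test_idx, lr, wd = 0,
                         radius = 0.1) {
  stopifnot(inherits(drill, "knet_drill"))
  decoded <- read_words(net, lexicon, test_idx)
  failed <- test_idx[decoded != test_idx]
  acc <- 1 - length(failed) / length(test_idx)
  n_trials <- 0L
  if (length(failed) > 0L && drill$reiterations > 0L) {
    order_idx <- rep(failed, drill$reiterations)
    res <- train_trials(net, lexicon, order_idx, "reading", lr = lr,
                        weight_decay = wd, freq_scale = rep(1, length(order_idx)),
                        radius = radius)
    net <- res$net
    n_trials <- length(order_idx)
  }
  list(net = net, accuracy = acc, n_failed = length(failed),
       n_trials = n_trials, drilled = failed)
}

#' Full developmental training run
#'
#' Initializes a network, runs the preliteracy phase (speaking/repetition),
#' freezes the weights between the phonetic output layer and the
#' semantic/phonetic input layers, then runs the literacy phase
#' (reading/comprehension/speaking/repetition) interleaved with drilling on
#' the lexicon's test set.
#'
#' @param lexicon A `knet_lexicon` with a selected test set.
#' @param spec A `knet_spec` (defaults to sizes matching the lexicon).
#' @param seed Simulation seed: derives the initial weights and all shuffles.
#' @param preliteracy,literacy Phase specifications.
#' @param drill Drill specification (or NULL to disable drilling).
#' @param radius Zero-error radius.
#' @return An object of class `knet_fit`: `net`, `log`, `drill_log`,
#'   `lexicon_seed`, `seed`.
#' @export
train_full <- function(lexicon, spec = NULL, seed = 1L,
                       preliteracy = phase_spec("preliteracy"),
                       literacy = phase_spec("literacy"),
                       drill = drill_spec(), radius = 0.1) {
  if (is.null(spec)) spec <- spec_for_lexicon(lexicon)
  net <- init_network(spec, seed = derive_seed(seed, "init"))
  test_idx <- match(lexicon$test_ids, lexicon$words$word_id)

  pre <- run_phase(net, lexicon, preliteracy,
                   seed = derive_seed(seed, "preliteracy"), radius = radius)
  net <- freeze_weights(pre$net, literacy_freeze_blocks(pre$net))
  lit <- run_phase(net, lexicon, literacy,
                   seed = derive_seed(seed, "literacy"), radius = radius,
                   drill = drill,
                   test_idx = if (length(test_idx)) test_idx else NULL)
  structure(list(net = lit$net,
                 log = rbind(pre$log, lit$log),
                 drill_log = lit$drill_log,
                 seed = as.integer(seed)),
            class = "knet_fit")
}

#' @export
print.knet_fit <- function(x, ...) {
  cat("<knet_fit> seed", x$seed, "-", nrow(x$log), "epoch-task log rows\n")
  if (nrow(x$drill_log) > 0) {
    cat("final drill-test accuracy:",
        round(utils::tail(x$drill_log$accuracy, 1), 3), "\n")
  }
  invisible(x)
}

#' Network specification sized to a lexicon
#'
#' @param lexicon A `knet_lexicon`.
#' @param hidden Hidden-layer size.
#' @param ... Passed to [network_spec()].
#' @return A `knet_spec` whose visual, phonetic and semantic layer sizes match
#'   the lexicon's pattern dimensions.
#' @export
spec_for_lexicon <- function(lexicon, hidden = 100L, ...) {
  network_spec(visual = ncol(lexicon$orthography),
               phonetic = ncol(lexicon$phonology),
               semantic = ncol(lexicon$semantics), hidden = hidden, ...)
}
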