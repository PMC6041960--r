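## Continuous-time layered sigmoid network: specification, initialization,
## forward dynamics, cross-entropy error, online BPTT updates, freezing.

TASKS <- list(
  reading       = list(clamp = "visual",         target = "phonetic_output"),
  comprehension = list(clamp = "visual",         target = "semantic"),
  speaking      = list(clamp = "semantic",       target = "phonetic_output"),
  repetition    = list(clamp = "phonetic_input", target = "phonetic_output")
)

#' Specify the dual-pathway network architecture
#'
#' Four primary systems (visual input, phonetic input, semantic, phonetic
#' output) are connected only through hidden layers, one per adjacent pair:
#' visual-semantic and semantic-phonetic output form the ventral (semantically
#' mediated) pathway; visual-phonetic input and phonetic input-phonetic output
#' form the dorsal (direct) pathway. All adjacent layers are fully connected
#' bidirectionally; the two directions are independent weight matrices.
#'
#' @param visual Units in the visual layer (twice the per-character bits).
#' @param phonetic Units in each phonetic layer (mora slots x features).
#' @param semantic Units in the semantic layer.
#' @param hidden Hidden-layer sizes: a single number for all four hidden
#'   layers, or a named vector with entries `vis_sem`, `vis_phin`,
#'   `sem_phout`, `phin_phout` to size each pathway's hidden layer
#'   separately (the ventral, semantically mediated pathway typically needs
#'   more capacity than the dorsal one).
#' @param n_timesteps Settling horizon (time steps per trial).
#' @param integration_rate Update weight of the time-integrated net input.
#' @param gain Input gain of the sigmoid.
#' @param error_window Time steps (1-based) over which output error is
#'   assessed; defaults to the final 5 steps.
#' @return An object of class `knet_spec`.
#' @export
network_spec <- function(visual = 60L, phonetic = 60L, semantic = 100L,
                         hidden = 100L, n_timesteps = 20L,
                         integration_rate = 0.1, gain = 1.0,
                         error_window = NULL) {
  h <- if (length(hidden) == 1L && is.null(names(hidden))) {
    c(vis_sem = hidden, vis_phin = hidden, sem_phout = hidden,
      phin_phout = hidden)
  } else {
    miss <- setdiff(c("vis_sem", "vis_phin", "sem_phout", "phin_phout"),
                    names(hidden))
    if (length(miss)) stop("hidden sizes missing for: ",
                           paste(miss, collapse = ", "))
    hidden
  }
  layers <- data.frame(
    name = c("visual", "hid_vis_sem", "semantic", "hid_vis_phin",
             "phonetic_input", "hid_sem_phout", "phonetic_output",
             "hid_phin_phout"),
    size = c(visual, h[["vis_sem"]], semantic, h[["vis_phin"]], phonetic,
             h[["sem_phout"]], phonetic, h[["phin_phout"]]),
    system = c("visual", "hidden", "semantic", "hidden", "phonetic_input",
               "hidden", "phonetic_output", "hidden"),
    stringsAsFactors = FALSE
  )
  pairs <- rbind(
    c("visual", "hid_vis_sem"), c("hid_vis_sem", "semantic"),
    c("visual", "hid_vis_phin"), c("hid_vis_phin", "phonetic_input"),
    c("semantic", "hid_sem_phout"), c("hid_sem_phout", "phonetic_output"),
    c("phonetic_input", "hid_phin_phout"),
    c("hid_phin_phout", "phonetic_output")
  )
  connections <- data.frame(
    from = c(pairs[, 1], pairs[, 2]),
    to = c(pairs[, 2], pairs[, 1]),
    stringsAsFactors = FALSE
  )
  connections$name <- paste0(connections$from, "->", connections$to)
  if (is.null(error_window)) {
    error_window <- (n_timesteps - 4L):n_timesteps
  }
  structure(list(layers = layers, connections = connections,
                 n_timesteps = as.integer(n_timesteps),
                 integration_rate = integration_rate, gain = gain,
                 error_window = as.integer(error_window)),
            class = "knet_spec")
}

#' @export
print.knet_spec <- function(x, ...) {
  cat("<knet_spec>", nrow(x$layers), "layers,", nrow(x$connections),
      "directed connection blocks,", x$n_timesteps, "time steps\n")
  invisible(x)
}

layer_index <- function(spec, name) {
  i <- match(name, spec$layers$name)
  if (any(is.na(i))) stop("unknown layer: ", paste(name[is.na(i)], collapse = ", "))
  i
}

#' Initialize a network state
#'
#' Weights and biases are drawn uniformly from \[-0.1, 0.1\]; nothing is
#' frozen or lesioned.
#'
#' @param spec A `knet_spec`.
#' @param seed Integer seed (distinct seeds give the distinct initial weight
#'   matrices used across simulations).
#' @return An object of class `knet_network`.
#' @export
init_network <- function(spec, seed = 1L) {
  with_seed(seed, {
    sizes <- spec$layers$size
    weights <- lapply(seq_len(nrow(spec$connections)), function(k) {
      nf <- sizes[layer_index(spec, spec$connections$from[k])]
      nt <- sizes[layer_index(spec, spec$connections$to[k])]
      matrix(stats::runif(nt * nf, -0.1, 0.1), nt, nf)
    })
    names(weights) <- spec$connections$name
    biases <- lapply(sizes, function(n) stats::runif(n, -0.1, 0.1))
    names(biases) <- spec$layers$name
    structure(list(spec = spec, weights = weights, biases = biases,
                   frozen = setNames(rep(FALSE, nrow(spec$connections)),
                                     spec$connections$name),
                   lesion = NULL, init_seed = as.integer(seed)),
              class = "knet_network")
  })
}

#' @export
print.knet_network <- function(x, ...) {
  nw <- sum(vapply(x$weights, length, integer(1)))
  cat("<knet_network>", nw, "weights;",
      sum(x$frozen), "frozen blocks;",
      if (is.null(x$lesion)) "no lesion" else
        paste0(length(x$lesion$units), " lesioned ", x$lesion$layer, " units"),
      "\n")
  invisible(x)
}

## 0-based connectivity indices for the C++ core
conn_indices <- function(net) {
  spec <- net$spec
  list(sizes = as.integer(spec$layers$size),
       from = layer_index(spec, spec$connections$from) - 1L,
       to = layer_index(spec, spec$connections$to) - 1L)
}

## a layer's bias stays trainable while at least one incoming block is
## unfrozen; freezing every incoming block freezes the bias with them
bias_free_layers <- function(net) {
  spec <- net$spec
  vapply(spec$layers$name, function(l) {
    inc <- spec$connections$name[spec$connections$to == l]
    length(inc) == 0L || any(!net$frozen[inc])
  }, logical(1), USE.NAMES = FALSE)
}

lesion_args <- function(net) {
  if (is.null(net$lesion)) {
    list(layer = -1L, units = integer(0))
  } else {
    list(layer = layer_index(net$spec, net$lesion$layer) - 1L,
         units = as.integer(net$lesion$units) - 1L)
  }
}

#' Run the forward settling dynamics for one input
#'
#' Clamps the task's input layer to `input` for all time steps; every other
#' unit starts from a zero integrated input (activation 0.5), updates its
#' integrated net input by `x <- x + rate * (s - x)` and squashes it with a
#' gain-1 logistic. Lesioned units output exactly 0 at every step.
#'
#' @param net A `knet_network`.
#' @param task One of `"reading"`, `"comprehension"`, `"speaking"`,
#'   `"repetition"`.
#' @param input Numeric vector matching the clamped layer's size.
#' @return List of layer-activation matrices (`size x (n_timesteps + 1)`,
#'   column 1 = initial state), named by layer.
#' @export
forward_pass <- function(net, task, input) {
  task <- match.arg(task, names(TASKS))
  spec <- net$spec
  cl <- layer_index(spec, TASKS[[task]]$clamp)
  if (length(input) != spec$layers$size[cl]) {
    stop("input length ", length(input), " != clamped layer size ",
         spec$layers$size[cl])
  }
  ci <- conn_indices(net)
  les <- lesion_args(net)
  A <- cpp_forward_traj(unname(net$weights), unname(net$biases), ci$sizes,
                        ci$from, ci$to, cl - 1L, as.numeric(input),
                        les$layer, les$units, spec$n_timesteps,
                        spec$integration_rate, spec$gain)
  if (any(!is.finite(A))) stop("non-finite activation in forward pass")
  offs <- cumsum(c(0L, spec$layers$size))
  out <- lapply(seq_len(nrow(spec$layers)), function(l) {
    A[(offs[l] + 1L):offs[l + 1L], , drop = FALSE]
  })
  names(out) <- spec$layers$name
  out
}

## final-step activations of `out_layer` for a matrix of inputs (one per row)
forward_batch <- function(net, task, inputs, out_layer = NULL) {
  task <- match.arg(task, names(TASKS))
  spec <- net$spec
  cl <- layer_index(spec, TASKS[[task]]$clamp)
  ol <- layer_index(spec, out_layer %||% TASKS[[task]]$target)
  ci <- conn_indices(net)
  les <- lesion_args(net)
  cpp_forward_batch(unname(net$weights), unname(net$biases), ci$sizes,
                    ci$from, ci$to, cl - 1L, as.matrix(inputs), ol - 1L,
                    les$layer, les$units, spec$n_timesteps,
                    spec$integration_rate, spec$gain)
}

#' Cross-entropy error with a zero-error radius
#'
#' Loss is `-sum(t*log(a) + (1-t)*log(1-a))`; the per-unit error derivative
#' `(a - t) / (a * (1 - a))` is zeroed wherever `|t - a| < radius`, so units
#' already close to target contribute no weight change.
#'
#' @param a Output activations in (0, 1); values of exactly 0 or 1 are clamped
#'   to a machine-epsilon margin with a warning.
#' @param target Target values in \[0, 1\].
#' @param radius Zero-error radius (default 0.1).
#' @return List with `loss` (scalar) and `deriv` (per-unit dE/da).
#' @export
cross_entropy_error <- function(a, target, radius = 0.1) {
  stopifnot(length(a) == length(target), radius >= 0)
  if (any(a <= 0 | a >= 1)) {
    warning("activations at 0/1 clamped away from the boundary")
    eps <- 1e-12
    a <- pmin(pmax(a, eps), 1 - eps)
  }
  loss <- -sum(target * log(a) + (1 - target) * log(1 - a))
  deriv <- (a - target) / (a * (1 - a))
  deriv[abs(target - a) < radius] <- 0
  list(loss = loss, deriv = deriv)
}

#' Freeze connection blocks
#'
#' Frozen blocks receive neither gradient updates nor weight decay; their
#' weights stay bit-identical under training.
#'
#' @param net A `knet_network`.
#' @param blocks Character vector of block names (`"from->to"`); an empty
#'   selector is a no-op.
#' @return The network with the blocks marked frozen.
#' @export
freeze_weights <- function(net, blocks) {
  if (length(blocks) == 0L) return(net)
  unknown <- setdiff(blocks, names(net$frozen))
  if (length(unknown) > 0L) {
    stop("unknown connection block(s): ", paste(unknown, collapse = ", "))
  }
  net$frozen[blocks] <- TRUE
  net
}

#' Blocks frozen after the preliteracy phase
#'
#' The forward projections linking the semantic and phonetic input layers to
#' the phonetic output layer (through their hidden layers):
#' `semantic -> hid_sem_phout -> phonetic_output` and
#' `phonetic_input -> hid_phin_phout -> phonetic_output`. Freezing these
#' fixes the production mappings acquired during preliteracy (speaking and
#' repetition) so literacy training cannot unlearn them. The feedback
#' directions stay trainable: weights into a clamped layer receive no
#' gradient, so the feedback blocks are still at their random initial values
#' at the end of preliteracy and must remain adjustable for the comprehension
#' and reading mappings to settle cleanly.
#'
#' @param net A `knet_network` (or `knet_spec`).
#' @return Character vector of block names.
#' @export
literacy_freeze_blocks <- function(net) {
  c("semantic->hid_sem_phout", "hid_sem_phout->phonetic_output",
    "phonetic_input->hid_phin_phout", "hid_phin_phout->phonetic_output")
}

## layer-pattern list (one matrix or NULL per layer) for the C++ trial runner
layer_patterns <- function(net, lexicon) {
  spec <- net$spec
  pats <- vector("list", nrow(spec$layers))
  pats[[layer_index(spec, "visual")]] <- lexicon$orthography
  pats[[layer_index(spec, "phonetic_input")]] <- lexicon$phonology
  pats[[layer_index(spec, "phonetic_output")]] <- lexicon$phonology
  pats[[layer_index(spec, "semantic")]] <- lexicon$semantics
  pats
}

#' Train the network on a sequence of trials (online backpropagation)
#'
#' Each trial clamps the task's input layer with the word's pattern, runs the
#' settling dynamics, backpropagates the cross-entropy error through the
#' unrolled time course, and applies
#' `delta_w = -lr * (freq_scale * dE/dw + weight_decay * w)` immediately
#' (no momentum). Frozen blocks are left untouched.
#'
#' @param net A `knet_network`.
#' @param lexicon A `knet_lexicon` providing the pattern matrices.
#' @param word_idx Integer word row indices, one per trial.
#' @param task Character task names, one per trial (or a single name).
#' @param lr Learning rate (> 0 to learn; 0 leaves weights unchanged).
#' @param weight_decay Weight-decay coefficient.
#' @param freq_scale Per-trial error-derivative multipliers (default 1).
#' @param radius Zero-error radius.
#' @param precision `"single"` (default; fast training arithmetic) or
#'   `"double"`. Frozen blocks and untouched parameters are returned
#'   bit-identical in either mode.
#' @return List with the updated `net` and per-trial `loss`.
#' @export
train_trials <- function(net, lexicon, word_idx, task, lr,
                         weight_decay = 0, freq_scale = NULL, radius = 0.1,
                         precision = c("single", "double")) {
  stopifnot(lr >= 0, weight_decay >= 0)
  precision <- match.arg(precision)
  n <- length(word_idx)
  if (length(task) == 1L) task <- rep(task, n)
  stopifnot(length(task) == n)
  if (is.null(freq_scale)) freq_scale <- rep(1, n)
  stopifnot(length(freq_scale) == n, all(freq_scale >= 0))
  spec <- net$spec
  ci <- conn_indices(net)
  bias_free <- bias_free_layers(net)
  clamp <- vapply(task, function(tk) layer_index(spec, TASKS[[tk]]$clamp),
                  integer(1)) - 1L
  target <- vapply(task, function(tk) layer_index(spec, TASKS[[tk]]$target),
                   integer(1)) - 1L
  res <- cpp_run_trials(unname(net$weights), unname(net$biases), ci$sizes,
                        ci$from, ci$to, unname(net$frozen), bias_free,
                        as.integer(word_idx) - 1L, clamp, target,
                        layer_patterns(net, lexicon), as.numeric(freq_scale),
                        lr, weight_decay, radius, spec$error_window,
                        spec$n_timesteps, spec$integration_rate, spec$gain,
                        TRUE, precision == "single")
  if (res$n_updates > 0L) {
    new_w <- setNames(res$weights, spec$connections$name)
    new_b <- setNames(res$biases, spec$layers$name)
    # frozen blocks / fully-frozen-bias layers never change: keep the
    # original doubles so they stay bit-identical across precision modes
    new_w[net$frozen] <- net$weights[net$frozen]
    new_b[!bias_free] <- net$biases[!bias_free]
    net$weights <- new_w
    net$biases <- new_b
  }
  list(net = net, loss = res$loss)
}

## loss and gradients for a single trial without updating (finite-difference
## testing hook)
trial_gradients <- function(net, lexicon, word_idx, task, radius = 0.1) {
  spec <- net$spec
  ci <- conn_indices(net)
  tk <- TASKS[[match.arg(task, names(TASKS))]]
  res <- cpp_run_trials(unname(net$weights), unname(net$biases), ci$sizes,
                        ci$from, ci$to, unname(net$frozen), bias_free_layers(net),
                        as.integer(word_idx) - 1L,
                        layer_index(spec, tk$clamp) - 1L,
                        layer_index(spec, tk$target) - 1L,
                        layer_patterns(net, lexicon), 1.0,
                        0, 0, radius, spec$error_window,
                        spec$n_timesteps, spec$integration_rate, spec$gain,
                        FALSE, FALSE)
  list(loss = res$loss[1],
       weights = setNames(res$grads$weights, spec$connections$name),
       biases = res$grads$biases)
}
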