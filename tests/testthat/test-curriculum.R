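# Curriculum bookkeeping on a deliberately tiny lexicon and network: the
# audits concern trial counts, schedules and freezing, not reading skill.

small_fit_bits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lex <- tiny_lexicon()
      spec <- tiny_spec(lex, hidden = 4, n_timesteps = 5)
      cache <<- list(lex = lex, spec = spec)
    }
    cache
  }
})

test_that("phase presentation mixes follow the curriculum", {
  pre <- phase_spec("preliteracy")
  expect_equal(pre$epochs, 20L)
  expect_equal(pre$presentations, list(speaking = 19L, repetition = 1L))
  expect_equal(pre$lr_start, 0.5)
  expect_equal(pre$lr_interval, 10L)
  lit <- phase_spec("literacy")
  expect_equal(lit$presentations,
               list(reading = 6L, comprehension = 12L, speaking = 1L,
                    repetition = 1L))
  expect_equal(lit$lr_interval, 2L)
  expect_equal(lit$wd_start, 5e-7)
})

test_that("per-epoch trial counts equal the presentation spec exactly", {
  b <- small_fit_bits()
  n <- nrow(b$lex$words)
  net <- init_network(b$spec, seed = 1)
  pre <- phase_spec("preliteracy", epochs = 2, lr_start = 0.05,
                    lr_decrement = 0.005)
  r <- run_phase(net, b$lex, pre, seed = 5)
  for (e in 1:2) {
    lg <- r$log[r$log$epoch == e, ]
    expect_equal(lg$n_trials[lg$task == "speaking"], 19 * n)
    expect_equal(lg$n_trials[lg$task == "repetition"], n)
  }
  lit <- phase_spec("literacy", epochs = 2, lr_start = 0.05,
                    lr_decrement = 0.005)
  r2 <- run_phase(r$net, b$lex, lit, seed = 6)
  lg <- r2$log[r2$log$epoch == 1, ]
  expect_equal(lg$n_trials[lg$task == "reading"], 6 * n)
  expect_equal(lg$n_trials[lg$task == "comprehension"], 12 * n)
  expect_equal(lg$n_trials[lg$task == "speaking"], n)
  expect_equal(lg$n_trials[lg$task == "repetition"], n)
})

test_that("lr/wd follow the closed-form schedules", {
  # literacy: lr at (1-based) epoch e is max(0, 0.5 - 0.05 * floor((e-1)/2))
  b <- small_fit_bits()
  net <- init_network(b$spec, seed = 2)
  lit <- phase_spec("literacy", epochs = 5)
  r <- run_phase(net, b$lex, lit, seed = 7)
  sched <- unique(r$log[, c("epoch", "lr", "wd")])
  expect_equal(sched$lr, sapply(1:5, function(e)
    max(0, 0.5 - 0.05 * ((e - 1) %/% 2))))
  expect_equal(sched$wd, sapply(1:5, function(e)
    max(0, 5e-7 - 5e-8 * ((e - 1) %/% 2))))
  # preliteracy interval is 10 epochs
  pre <- phase_spec("preliteracy", epochs = 11)
  expect_equal(sapply(1:11, function(e)
    kanjinet:::schedule_value(pre$lr_start, pre$lr_decrement,
                              pre$lr_interval, e - 1)),
    c(rep(0.5, 10), 0.45))
  # underflow clamps at zero with a warning
  fast <- phase_spec("literacy", epochs = 3, lr_start = 0.01,
                     lr_decrement = 0.02, lr_interval = 1)
  expect_warning(run_phase(init_network(b$spec, seed = 1), b$lex, fast,
                           seed = 1), "underflow")
})

test_that("epochs = 0 returns the state unchanged", {
  b <- small_fit_bits()
  net <- init_network(b$spec, seed = 3)
  r <- run_phase(net, b$lex, phase_spec("literacy", epochs = 0), seed = 1)
  expect_identical(r$net$weights, net$weights)
  expect_equal(nrow(r$log), 0)
})

test_that("frequency scaling is sqrt-proportional and drilling is unscaled", {
  expect_equal(root_frequency(4), 2)
  expect_equal(root_frequency(c(1, 9, 100)), c(1, 3, 10))
  d <- drill_spec()
  expect_false(d$frequency_scaling)
  expect_equal(d$test_every, 2L)
  expect_equal(d$reiterations, 20L)
})

test_that("drilling trains only failed items, 20 trials each", {
  b <- small_fit_bits()
  net <- init_network(b$spec, seed = 4)
  idx <- match(b$lex$test_ids, b$lex$words$word_id)
  d <- run_drilling(net, b$lex, drill_spec(), idx, lr = 0.05)
  decoded <- read_words(net, b$lex, idx)
  failed <- idx[decoded != idx]
  expect_equal(d$n_failed, length(failed))
  expect_setequal(d$drilled, failed)
  expect_equal(d$n_trials, 20 * length(failed))
  expect_equal(d$accuracy, 1 - length(failed) / length(idx))
  # if everything were already correct no trials would run
  if (length(failed) == 0) expect_equal(d$n_trials, 0)
})

test_that("train_full freezes the output pathways across literacy", {
  b <- small_fit_bits()
  pre <- phase_spec("preliteracy", epochs = 1, lr_start = 0.05,
                    lr_decrement = 0.005)
  lit <- phase_spec("literacy", epochs = 2, lr_start = 0.05,
                    lr_decrement = 0.005)
  fit <- train_full(b$lex, b$spec, seed = 77, preliteracy = pre,
                    literacy = lit, drill = drill_spec(reiterations = 2))
  # recompute the end-of-preliteracy state independently
  net0 <- init_network(b$spec, seed = kanjinet:::derive_seed(77, "init"))
  r1 <- run_phase(net0, b$lex, pre,
                  seed = kanjinet:::derive_seed(77, "preliteracy"))
  frozen_blocks <- literacy_freeze_blocks(net0)
  for (blk in frozen_blocks) {
    expect_identical(fit$net$weights[[blk]], r1$net$weights[[blk]])
  }
  # phase log covers both phases; drill log has one row per scheduled test
  expect_setequal(unique(fit$log$phase), c("preliteracy", "literacy"))
  expect_equal(nrow(fit$drill_log), 1)
})

test_that("training is deterministic given the simulation seed", {
  b <- small_fit_bits()
  pre <- phase_spec("preliteracy", epochs = 1, lr_start = 0.05,
                    lr_decrement = 0.005)
  lit <- phase_spec("literacy", epochs = 1, lr_start = 0.05,
                    lr_decrement = 0.005)
  f1 <- train_full(b$lex, b$spec, seed = 5, preliteracy = pre,
                   literacy = lit, drill = drill_spec(reiterations = 1))
  f2 <- train_full(b$lex, b$spec, seed = 5, preliteracy = pre,
                   literacy = lit, drill = drill_spec(reiterations = 1))
  expect_identical(f1$net$weights, f2$net$weights)
  expect_identical(f1$log, f2$log)
  f3 <- train_full(b$lex, b$spec, seed = 6, preliteracy = pre,
                   literacy = lit, drill = drill_spec(reiterations = 1))
  expect_false(identical(f1$net$weights, f3$net$weights))
})
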