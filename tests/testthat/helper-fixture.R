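# Shared synthetic benchmark fixture and trained-model cache.
#
# The benchmark: 300 cells x 200 genes x 300 peaks, 4 planted types,
# 2 planted states. Stage-1 training uses the fixture schedule from the
# vignette (200 or 600 epochs depending on the check); results are
# cached per (seed, epochs, ablation) so several test files can share
# one training run.

.fixture_env <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_pair(sim_config(seed = 1))
  .fixture_env$sim
}

# fixture stage-1 schedules: "slow" preserves secondary (state)
# structure best; "fast" is used for the many-run ablation comparison
fixture_stage1_cfg <- function(seed, schedule = c("slow", "fast"), ...) {
  schedule <- match.arg(schedule)
  base <- if (schedule == "slow")
    list(epochs = 250, learning_rate = 1e-3)
  else
    list(epochs = 200, learning_rate = 3e-3)
  do.call(fusion_config, utils::modifyList(c(base, list(seed = seed)), list(...)))
}

fixture_stage1 <- function(seed, schedule = "slow", ...) {
  key <- paste0("st1_", schedule, "_", seed, "_",
                paste(deparse(substitute(list(...))), collapse = ""))
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- train_stage1(fixture_sim()$omics,
                                        fixture_stage1_cfg(seed, schedule, ...))
  .fixture_env[[key]]
}

fixture_stage2 <- function(seed) {
  key <- paste0("st2_", seed)
  if (is.null(.fixture_env[[key]])) {
    st1 <- fixture_stage1(seed, "slow")
    .fixture_env[[key]] <- train_stage2(st1$latents$ZI,
                                        multiclust_config(seed = seed))
  }
  .fixture_env[[key]]
}
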