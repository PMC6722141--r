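# Standard phantom benchmark (2 clusters x 6 images, 64^3, inter 4 voxels,
# intra 1.5 voxels, noise 2 intensity units = 2% of the template's dynamic
# range), registered with the default HMRML configuration. Runs are cached
# so that several tests can assert different properties of the same run.
.bench_cache <- new.env(parent = emptyenv())

standard_population <- function(seed) {
  key <- paste0("pop_", seed)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- generate_population(phantom_spec(seed = seed))
  .bench_cache[[key]]
}

standard_benchmark <- function(seed, mode = "HMRML") {
  key <- paste0(mode, "_", seed)
  if (is.null(.bench_cache[[key]])) {
    pop <- standard_population(seed)
    cfg <- if (mode == "HUGS") run_config(mode = "HUGS", schedule = 1)
           else run_config()
    res <- run_multiresolution(pop$images, cfg)
    .bench_cache[[key]] <- list(
      pop = pop, res = res,
      ssd_pre = mean_pairwise_ssd(pop$images),
      ssd_post = mean_pairwise_ssd(res$warped),
      dice_pre = evaluate_run(NULL, pop$label_masks)$overall,
      dice_post = evaluate_run(res, pop$label_masks)$overall)
  }
  .bench_cache[[key]]
}

trace_is_monotone <- function(trace, step_tol = 0.01) {
  length(trace) < 2 ||
    all(diff(trace) <= step_tol * utils::head(trace, -1) + 1e-9)
}
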