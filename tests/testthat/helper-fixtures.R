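# Shared fixtures, built once per test run.

hk_cache <- new.env(parent = emptyenv())

# Seed-1 synthetic dual-input pair, memoised.
hk_inputs <- function(seed = 1L) {
  key <- paste0("inp", seed)
  if (is.null(hk_cache[[key]])) hk_cache[[key]] <- gen_inputs(seed)
  hk_cache[[key]]
}

hk_sched16 <- default_schedule(FALSE)
hk_sched17 <- default_schedule(TRUE)

hk_p4_hcc <- default_group_params("4C", "HCC")$mean
hk_p4_liver <- default_group_params("4C", "liver")$mean
hk_p3_hcc <- default_group_params("3C", "HCC")$mean

# Fast fitting configuration for unit tests.
hk_quick_cfg <- function(n_starts = 6, ...) {
  fit_config(n_starts = n_starts, max_iter = 200, tol = 1e-10, ...)
}

params_vec <- function(p) unlist(unclass(p))

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
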