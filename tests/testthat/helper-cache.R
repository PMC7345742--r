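# Fits on the two cohort sizes the recovery criteria prescribe are expensive;
# memoise them so the acceptance and estimation files share one computation.
.fit_cache <- new.env(parent = emptyenv())

cached_sim_fit <- function(n, seed = 1) {
  key <- paste0("n", n, "s", seed)
  if (is.null(.fit_cache[[key]])) {
    sim <- simulate_cohort(cohort_config(n = n, seed = seed))
    .fit_cache[[key]] <- list(sim = sim, fit = fit(sim$dataset))
  }
  .fit_cache[[key]]
}
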