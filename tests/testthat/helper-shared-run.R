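# One moderately sized virtual-colony run shared across test files (built
# lazily, once per test session): 4 mice (3 treatment, 1 control), 14 days,
# default noise -- the desk-scale analogue of the two-month cage study.
shared_colony_run <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$run))
      cache$run <- run_colony(system_config(), make_profiles(3, 1),
                              days = 14, seed = 20240101)
    cache$run
  }
})
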