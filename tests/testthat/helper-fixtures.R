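# Small configurations used across tests; sizes chosen so the whole suite
# stays fast while every code path is exercised.

tiny_config <- function(seed = 1, ...) {
  args <- list(n_native_nonwoody = 4, n_native_woody = 4,
               n_nonnative_nonwoody = 4, n_nonnative_woody = 4,
               n_families = 4, genera_per_family = 6,
               max_cells = 500, seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

small_config <- function(seed = 1, ...) {
  args <- list(n_native_nonwoody = 150, n_native_woody = 60,
               n_nonnative_nonwoody = 120, n_nonnative_woody = 90,
               n_families = 15, genera_per_family = 8,
               max_cells = 1500, seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# full synthetic dataset generated once and reused by read-only tests
synth_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config(seed = 99)
      fl <- generate_flora(cfg)
      gi <- quiet(generate_interactions(fl, cfg))
      cache <<- list(config = cfg, flora = fl, interactions = gi$interactions,
                     truth = gi$truth)
    }
    cache
  }
})
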