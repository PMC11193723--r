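# Shared fixtures: the frozen parameter set and a few cached steady
# states reused across model tests.

params <- default_parameters()

cached_ss <- local({
  cache <- new.env(parent = emptyenv())
  function(glc, lac, level) {
    key <- paste(glc, lac, level, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- steady_state(params, external_conditions(glc, lac),
                                   level)
    cache[[key]]
  }
})
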