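# One full pipeline run on the default synthetic cohort, shared by the
# acceptance tests (memoized: computed on first use).
e2e_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- runPipeline(pipelineConfig(outDir = NULL, seed = 42))
    cache
  }
})
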