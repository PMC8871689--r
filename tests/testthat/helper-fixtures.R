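# Shared fixtures, built lazily and cached for the session.

# The reference synthetic benchmark: 20 segments of 600 s at 10 Hz,
# default artifact spec, master seed 1.
getBenchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeBenchmark(20L, 600, 10, seed = 1L)
    cache
  }
})

# benchmark table for the proposed method at default config, cached
getProposedTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- runBenchmark(getBenchmark(), methods = "proposed")
    cache
  }
})

# one small noised dataset for unit tests
smallDataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- injectArtifacts(generateClean(600, 10, seed = 11),
                                seed = 12)
    cache
  }
})

expect_same_annotation <- function(a, b) {
  expect_identical(annotationToDf(a), annotationToDf(b))
}
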