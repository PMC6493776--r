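# shared fixtures, built once per test run (cached in the package's own
# session caches where applicable)

toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- toy_ring(N = 64)
    cache
  }
})

toy_fixture_128 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- toy_ring(N = 128)
    cache
  }
})

# reference conductance-LIF network (tuned, calibrated); heavy, cached by
# reference_network() itself
ref_fixture <- function() reference_network()

expect_rel_equal <- function(actual, expected, tol, label = NULL) {
  testthat::expect_lt(max(abs(actual - expected) / pmax(abs(expected),
                                                        .Machine$double.eps)),
                      tol, label = label)
}
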