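# build the 17-record fixture once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed = 42) {
  key <- as.character(seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- build_fixture(seed = seed)
  }
  .fixture_cache[[key]]
}
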