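# Shared fixtures that are expensive to build (trained models) are cached
# across test files within one run.
.earcount_test_cache <- new.env(parent = emptyenv())
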