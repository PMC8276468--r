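# The default synthetic bundle (5 hosts x 50 kb, seed 42) is used by several
# recovery tests; generate it once per test run.
.bundle_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.bundle_cache$b)) {
    .bundle_cache$b <- synthesize_metagenome(synthetic_config(seed = 42L))
  }
  .bundle_cache$b
}

# a small, fast config for structural tests; any field can be overridden
small_config <- function(...) {
  args <- utils::modifyList(
    list(seed = 7L, n_hosts = 3L, host_length = 15000L,
         prophage_length_range = c(3000L, 4000L), n_spacer_arrays = 3L,
         n_reads = 2000L),
    list(...)
  )
  do.call(synthetic_config, args)
}
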