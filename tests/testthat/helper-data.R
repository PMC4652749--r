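# Shared synthetic datasets, generated once per test run on first use.
# Seed 101 is the study condition for every recovery check; the generator's
# defaults (2000 genes, two ~2 Mb chromosomes) are what the package
# documents as its reference simulation size.

.shared <- new.env(parent = emptyenv())

shared_config <- function() generator_config(seed = 101L)

shared_dataset <- function() {
  if (is.null(.shared$wt)) .shared$wt <- generate_dataset(shared_config())
  .shared$wt
}

shared_mutant <- function() {
  if (is.null(.shared$mut))
    .shared$mut <- generate_mutant(shared_config(), shared_dataset())
  .shared$mut
}
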