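# Shared fixtures, generated once per test session. The default bundle
# reproduces the study conditions (seed 42, 30 known + 20 novel planted
# miRNAs, 20 shuffled decoys, 100k reads per library); the small bundle
# keeps the same structure at a size suitable for module tests.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(seed = 11L, outdir) {
  synthetic_config(seed = seed, n_unigenes = 60L, n_known_mirnas = 6L,
                   n_novel_mirnas = 4L, n_decoy_mirnas = 4L,
                   reads_per_library = 20000L, n_target_sites = 8L,
                   degradome_tags_per_library = 6000L, outdir = outdir)
}

small_bundle <- function() {
  if (is.null(.fixtures$small_bundle)) {
    dir <- file.path(tempdir(), "dgr-small-bundle")
    .fixtures$small_bundle <- generate_dataset(small_config(outdir = dir))
  }
  .fixtures$small_bundle
}

small_run <- function() {
  if (is.null(.fixtures$small_run)) {
    b <- small_bundle()
    cfg <- pipeline_config_from_bundle(
      b, outdir = file.path(tempdir(), "dgr-small-run"), seed = 7L,
      params = list(degradome = list(n_perm = 200L)))
    .fixtures$small_run <- suppressWarnings(run_all(cfg))
  }
  .fixtures$small_run
}

default_bundle <- function() {
  if (is.null(.fixtures$default_bundle)) {
    dir <- file.path(tempdir(), "dgr-default-bundle")
    .fixtures$default_bundle <-
      generate_dataset(synthetic_config(seed = 42L, outdir = dir))
  }
  .fixtures$default_bundle
}

default_run <- function() {
  if (is.null(.fixtures$default_run)) {
    cfg <- pipeline_config_from_bundle(
      default_bundle(), outdir = file.path(tempdir(), "dgr-default-run"),
      seed = 42L)
    .fixtures$default_run <- suppressWarnings(run_all(cfg))
  }
  .fixtures$default_run
}

truth_field <- function(truth, field) {
  vapply(truth$planted_mirnas, function(p) {
    v <- p[[field]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
}

# a tiny hand-built tag_set
toy_tags <- function(reads) filter_and_collapse(reads)
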