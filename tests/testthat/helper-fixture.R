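# The bundled synthetic study (seed 42) and its pipeline run, built once and
# shared across test files.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- synthetic_dataset(seed = 42L)
  }
  .fixture_env$ds
}

get_annotation <- function() {
  if (is.null(.fixture_env$ann)) {
    ds <- get_fixture()
    .fixture_env$ann <- run_pipeline(ds$genome, ds$reads_by_tissue,
                                     ds$truth$features, ds$ref_hairpins,
                                     ds$ref_matures, ds$existing_annotation)
  }
  .fixture_env$ann
}
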