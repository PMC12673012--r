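# Shared expensive fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# default-condition Mueller-matrix library for the three benchmark classes
fixture_library <- function() {
  if (is.null(.fixtures$lib)) {
    specs <- list(stress_preset("normal"), stress_preset("spherocyte"),
                  stress_preset("echinocyte"))
    .fixtures$lib <- build_mm_library(specs, seed = 1)
  }
  .fixtures$lib
}
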