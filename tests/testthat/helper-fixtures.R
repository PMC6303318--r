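# Shared fixtures: a fixed 700-nt random reference and a small canonical
# simulated library. Everything is generated in code; nothing is stored.

fixture_ref <- function(len = 700L, seed = 1L, ...) {
  random_reference(len, seed = seed, ...)
}

fixture_config <- function(n, seed = 42L, ...) {
  ref <- fixture_ref()
  simulation_config(
    n,
    class_fraction_probs(ref, c(sub_mature = 0.05, mature = 0.55,
                                exS = 0.25, exL = 0.15)),
    seed = seed, ...)
}

# reference segment of length L ending at coordinate end (error free)
ref_segment <- function(model, end, L) {
  substr(model$sequence, end - L + 1L, end)
}

# assemble a raw read: insert + linker (+ barcode + filler)
make_read <- function(model, insert, barcode = strrep("T", 10L),
                      filler = "") {
  paste0(insert, model$linker, barcode, filler)
}
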