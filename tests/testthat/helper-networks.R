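# Shared fixtures: built once per test run. Small networks are cheap; the
# default 51-species network is reused across files.
default_net <- build_network()
perface_net <- build_network(affinities = bmp_affinities(het_typeii = "per-face"))

HH <- "Bmp2/7-Acvr1-BmpR1-(TypeII)2"

# one mid-grid parameter set used in several places
mid_params <- tibble::tibble(
  "Bmp2/2" = 0.1, "Bmp7/7" = 0.1, "Bmp2/7" = 0.1,
  BmpR1 = 10, Acvr1 = 10, TypeII = 10, gamma = 100
)

# relative difference with a floor for near-zero species
rel_diff <- function(a, b, floor = 1e-12) {
  abs(a - b) / pmax(abs(b), floor)
}
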