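# canonical ground-truth parameter sets used across tests

ternary_truth <- function() {
  rate_params(k2 = 100, km2 = 5000, k3 = 100, km3 = 20000, k4 = 50, km4 = 12)
}

induced_fit_truth <- function() {
  rate_params(k1 = 10, km1 = 100, kconf = 40, kmconf = 2)
}

# minimal catalytic cycle: binding, chemistry, release (1/(uM s), 1/s)
cycle_truth <- function(krel = 20) {
  rate_params(kon = 10, koff = 20, kchem = 2, krel = krel)
}

# kobs generators for secondary-plot studies
kobs_hyp <- function(S, KD1 = 10, kconf = 40, kmconf = 2) {
  kmconf + kconf * S / (KD1 + S)
}
kobs_lin <- function(S, k1 = 0.05, km1 = 4) km1 + k1 * S

pfo_design <- function() c(0.5, 1, 2, 5, 10, 20, 40)

init_vector_for_test <- function(scheme, init) {
  y0 <- stats::setNames(numeric(nrow(scheme$species)), scheme$species$name)
  y0[names(init)] <- init
  y0
}
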