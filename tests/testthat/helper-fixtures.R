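# Shared fixtures. Networks and vehicle steady states are cached across
# test files (same defaults everywhere) so the suite does not re-solve
# identical problems.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

het_network <- function() {
  .cached("het", function() build_network(heterozygous_g12c_pools(),
                                          base_parameters()))
}

hom_network <- function() {
  .cached("hom", function() build_network(homozygous_g12c_pools(),
                                          base_parameters()))
}

wt_network <- function() {
  .cached("wt", function() build_network(all_wt_pools(), base_parameters()))
}

g12v_network <- function() {
  .cached("g12v", function() build_network(heterozygous_g12v_pools(),
                                           base_parameters()))
}

het_vehicle <- function() {
  .cached("het_ss", function() find_steady_state(het_network()))
}

hom_vehicle <- function() {
  .cached("hom_ss", function() find_steady_state(hom_network()))
}

wt_vehicle <- function() {
  .cached("wt_ss", function() find_steady_state(wt_network()))
}

# small 4 x 4 dose ladders around the working doses (M; native units)
small_g12ci_doses <- function() c(0, 62.5, 250, 1000) * 1e-9
small_egfri_doses <- function() c(0, 0.25, 1, 4)

small_het_grid <- function() {
  .cached("het_grid4", function() {
    dose_response_grid(het_network(), small_g12ci_doses(),
                       small_egfri_doses(),
                       egfri_template = egfr_inhibition(dose = 0, ic50 = 0.2))
  })
}

# per-pool closed-form total: production / degradation
expected_pool_total <- function(network, pool_name) {
  network$production[[pool_name]] / network$base$ras_degradation
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), 1e-300)
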