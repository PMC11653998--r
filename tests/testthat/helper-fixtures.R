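# Shared fixtures: noise-free series builders and representative parameter
# sets spanning the reference panel's range.

p_glucose <- gompertz_params(1617.67, 870.77, 28.37)  # steep screening curve
p_mixture <- gompertz_params(991.00, 236.31, 33.92)   # 1:1 WMP:MP mixture
p_generic <- gompertz_params(1000, 250, 30)

noise_free_series <- function(params, grid = seq(0, 96, by = 2),
                              condition = "fixture", replicate = 1) {
  gas_series(condition, replicate, grid, gompertz_cumulative(params, grid))
}

# deduplicated parameter triples of the bundled reference panel
panel_triples <- function() {
  tab <- reference_panel()
  unique(tab[, c("h_max", "r_max", "lag")])
}
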