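# study design at reduced grid resolution: same five-origin peak design and
# cohort size as the defaults, coarser axes and smaller forests so the full
# pipeline runs in seconds
small_gen_config <- function(seed, ...) {
  generator_config(n_per_class = 12, lc_points = 1201, ftir_points = 869,
                   shift_sd = 2, seed = seed, ...)
}

small_exp_config <- function(seed, ...) {
  experiment_config(generator = small_gen_config(seed),
                    ntree_init = 300, mtry_span = 3, boruta_trees = 300,
                    boruta_max_iter = 40, max_lv = 8, seed = seed, ...)
}

# a smooth random signal with variance in every segment (for COW tests)
smooth_signal <- function(n, seed, window = 11) {
  set.seed(seed)
  pad <- (window - 1) / 2
  x <- stats::filter(stats::rnorm(n + 2 * pad), rep(1 / window, window),
                     sides = 2)
  as.numeric(x[(pad + 1):(pad + n)])
}
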