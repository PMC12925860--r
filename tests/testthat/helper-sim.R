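# shared fixtures, built in code

# a well-identified reference observer (bias exactly 8)
ref_observer <- function(bias = 8, v_slope = 0.3, a = 1.2, z_r = 0.5,
                         t0 = 0.25) {
  ddm_params(v_int = -bias * v_slope, v_slope = v_slope, a = a, z_r = z_r,
             t0 = t0)
}

# the 450-stimulus morph sequence (each morph 30 times), fixed order
full_morph_sequence <- function() rep(1:15, 30)

# hand-built tiny trial table
toy_trials <- function() {
  data.frame(participant = rep(c("p1", "p2"), each = 5),
             run = 1L,
             s = c(1L, 8L, 15L, 8L, 1L, 15L, 8L, 1L, 8L, 15L),
             choice = c("happy", "angry", "angry", "happy", "happy",
                        "angry", "angry", "happy", "happy", "angry"),
             rt = c(0.45, 0.61, 0.52, 0.73, 0.38, 0.44, 0.59, 0.41, 0.66, 0.5),
             stringsAsFactors = FALSE)
}

# binomial-noise group psychometric data from a 4PL truth
gen_4pl_props <- function(x0, n_total, seed, gamma = 0.02, lam = 0.98,
                          beta = 1.5) {
  set.seed(seed)
  s <- 1:15
  p <- gamma + (lam - gamma) / (1 + exp(-beta * (s - x0)))
  rbinom(15, n_total, p) / n_total
}
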