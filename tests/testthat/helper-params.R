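# default parameter set and common variants used across tests
p_default <- table2_params()

p_beta <- function(b) update_params(p_default, beta = b)

# random admissible parameter draws around the default set (log-uniform on
# broad ranges); used by the property-style scans
draw_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    runi <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
    model_params(Lambda = runi(1, 20), k = runif(1, 0, 2),
                 mu = runi(0.1, 1), beta = runi(0.01, 2),
                 omega = runi(0.1, 1), delta = runi(0.1, 1),
                 m = runi(0.5, 8), a = runi(0.2, 2),
                 n = runi(0.2, 2), d = runi(0.1, 1),
                 alpha = runif(1, 0.6, 1))
  })
}

# random admissible states for Jacobian checks
draw_states <- function(n, seed, scale = 20) {
  set.seed(seed)
  lapply(seq_len(n), function(i) runif(3, 0, scale))
}
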