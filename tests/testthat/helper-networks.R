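# Networks and parameter draws shared across test files.

fig_params <- function(...) network_params(...)  # canonical defaults

fig_net <- function() build_wta(4)  # 4 excitatory + 1 shared inhibitory

# Random parameter set inside the contraction bounds, including their
# leak-generalized counterparts (the printed bounds assume unit leaks):
#   - beta1*beta2 ~ U(0.3, 0.95), alpha1 ~ U(1 + eps, 2*sqrt(b1b2) - eps)
#   - expansion: alpha1 > G_exc (self-excitation beats the leak)
#   - winner contraction: beta1*beta2 > (alpha1 - G_exc) * G_inh (det > 0)
#     and alpha1 - G_exc < G_inh (trace < 0)
random_valid_params <- function() {
  repeat {
    bb <- runif(1, 0.3, 0.95)
    beta1 <- runif(1, 0.5, 4)
    beta2 <- bb / beta1
    hi <- 2 * sqrt(bb)
    if (hi <= 1.02) next
    alpha1 <- runif(1, 1.01, hi - 0.01)
    g_exc <- runif(1, 0.9, 1.3)
    g_inh <- runif(1, 0.9, 1.6)
    if (alpha1 <= g_exc + 0.02) next
    if (bb <= (alpha1 - g_exc) * g_inh + 0.02) next
    if (alpha1 - g_exc >= g_inh - 0.02) next
    p <- network_params(alpha1 = alpha1, beta1 = beta1, beta2 = beta2,
                        g_exc = g_exc, g_inh = g_inh)
    if (length(validate_params(p)) == 0) return(p)
  }
}

all_patterns <- function(tab) attr(tab, "subspaces")
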