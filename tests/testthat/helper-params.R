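# Small helpers shared across the suite.

# random positive parameter set with all decays > 0 (for property tests)
random_params <- function(k_pair = stats::runif(1, 0, 2)) {
  digitalizer_params(
    alpha_R = stats::runif(1, 1, 20),
    beta_R = stats::runif(1, 0, 1),
    K_TF = stats::runif(1, 10, 200),
    n_act = sample(1:4, 1),
    alpha_S = stats::runif(1, 0, 20),
    K_R = stats::runif(1, 10, 5000),
    n_rep = sample(1:4, 1),
    k_pair = k_pair,
    delta_mR = stats::runif(1, 0.05, 0.5),
    delta_mS = stats::runif(1, 0.05, 0.5),
    delta_R = stats::runif(1, 0.01, 0.1),
    delta_G = stats::runif(1, 0.01, 0.1),
    lambda_R = stats::runif(1, 0.5, 5),
    lambda_G = stats::runif(1, 0.5, 5),
    mu = 0)
}

random_state <- function() {
  c(mR = stats::runif(1, 0, 50), mS = stats::runif(1, 0, 50),
    R = stats::runif(1, 0, 500), G = stats::runif(1, 0, 500))
}

# parameter set with a strong transcriptional repressor and a large sRNA pool;
# the regime where the mutual-inhibition loop locks into two stable branches
bistable_params <- function() {
  digitalizer_params(alpha_S = 50, K_R = 20, beta_R = 0.5)
}
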