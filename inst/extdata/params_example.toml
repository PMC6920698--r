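# Construct presets for the digitalizer model (all rates nM/min, times min).
# One section per plasmid variant; missing keys fall back to package defaults.

[digitalized]
alpha_R = 10
beta_R = 0.075
K_TF = 100
n_act = 2
alpha_S = 5
K_R = 5000
n_rep = 2
k_pair = 1
delta_mR = 0.2
delta_mS = 0.2
delta_R = 0.01
delta_G = 0.01
lambda_R = 2
lambda_G = 2
mu = 0

[non_digitalized]
alpha_R = 10
beta_R = 0.075
K_TF = 100
alpha_S = 0

[promoterless]
alpha_R = 0
beta_R = 0
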