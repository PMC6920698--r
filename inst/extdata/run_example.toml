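# End-to-end pipeline configuration: simulate -> generate -> summarise -> fit.

[run]
seed = 1
n_events = 2000
strengths = [0.3, 1, 3, 10, 30]
gate_q = 0.995
fit_free = "k_pair"
n_starts = 10

[design]
constructs = ["digitalized", "non_digitalized", "promoterless"]
doses = [0, 10, 50, 200, 1000]
times = [0, 5, 20, 60, 160, 1440]

[noise]
gain = 4
sigma_ext = 0.3
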