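# Beis-genotype scenario: near-complete CI partitioned 98:2 between
# female-mortality and male-development outcomes, 1.8% imperfect maternal
# transmission, invasion from a 50% founding infection frequency.
sigma_fm: 0.98
sigma_md: 0.02
sigma_total: 1
mu: 0.018
omega0: 0.5
replicates: 100
base_seed: 1
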