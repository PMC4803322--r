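# SynEx circuit (n = ComK, m = MecA).
# Units: molecule numbers and hours. Reconstructed parameter set: the ComK module
# mirrors the native circuit (k_k = 5 from the published high-copy variant
# 5000/1000); the MecA arm is designed so that (i) the rest state holds both
# species at low copy number, (ii) the competent state holds both high, and
# (iii) the deterministic oscillatory window spans alpha_k^(1) ~ 0.54/h to
# alpha_k^(2) ~ 10.9/h.  See the methods vignette.
alpha_k    0.1     # ComK basal induction rate, molecules/hour (control parameter; scans override)
beta_k     136     # ComK auto-activation maximal rate, molecules/hour (time-rescaled)
k_k        5       # ComK auto-activation half-point, molecules (published high-copy variant 5000 / 1000)
h          2       # ComK activation Hill coefficient (lineage value)
alpha_m    0.17    # MecA basal production, molecules/hour (rest MecA ~ 0.17 molecules: low copy at rest)
beta_m     85      # MecA ComK-activated production, molecules/hour (competent-state MecA ~ 85 molecules)
k_m        2.5     # MecA activation half-point, molecules (published high-copy variant 2500 / 1000)
p          5       # MecA activation Hill coefficient (mirrors the native repression exponent)
delta      0.17    # per-MecA-molecule enzymatic ComK degradation, 1/(molecule x hour)
lambda_k   3.4     # linear ComK degradation, 1/hour (stabilises the rest state; MecA is scarce there)
lambda_m   1.0     # linear MecA degradation, 1/hour (sets the negative-feedback delay)
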