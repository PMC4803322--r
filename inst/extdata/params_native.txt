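# Native competence circuit (n = ComK, m = ComS).
# Units: molecule numbers and hours. Reconstructed parameter set: values derive
# from the published two-component reduction of the ComK/ComS/MecA system
# (dimensionless Hill exponents and the Michaelis constants kept from that
# lineage), with the molecule-number scale set by Gamma_k = 25, Gamma_s = 20 and
# the overall time scale chosen so the deterministic regime boundaries fall at
# alpha_k^(1) ~ 0.64/h and alpha_k^(2) ~ 1.86/h.  See the methods vignette.
alpha_k    0.1     # ComK basal induction rate, molecules/hour (control parameter; scans override)
beta_k     39      # ComK auto-activation maximal rate, molecules/hour (reconstructed, time-rescaled)
k_k        8       # ComK auto-activation half-point, molecules (design choice: places the spiral fixed point on the rising Hill flank)
h          2       # ComK activation Hill coefficient (lineage value)
alpha_s    0       # ComS basal production, molecules/hour (lineage value: ComS expression is fully ComK-repressible)
beta_s     39      # ComS maximal (unrepressed) production, molecules/hour (sized so the rest state holds ~85 ComS)
k_s        5.55    # ComS repression half-point, molecules (lineage value 0.222 x Gamma_k)
p          5       # ComS repression Hill coefficient (lineage value)
delta_k    5.2     # maximal MecA-mediated ComK degradation, 1/hour (time-rescaled)
delta_s    1.04    # maximal MecA-mediated ComS degradation, 1/hour (slower than ComK: the negative-feedback arm must lag to oscillate)
Gamma_k    25      # Michaelis constant for ComK, molecules (published high-copy variant 25000 / 1000)
Gamma_s    20      # Michaelis constant for ComS, molecules (published high-copy variant keeps 20)
lambda_k   0.26    # linear (dilution) ComK degradation, 1/hour (bounds the high-induction state)
lambda_s   0.26    # linear (dilution) ComS degradation, 1/hour (same dilution as ComK)
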