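# vibronic mode table, state_basis=neutral
omega_cm1	huang_rhys	lambda_eV	assignment
778	0	0	bend
2149	1.978	0.527	C=N stretch
3500	0.084	0.036	C-H stretch
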