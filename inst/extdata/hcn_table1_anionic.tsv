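# vibronic mode table, state_basis=charged
omega_cm1	huang_rhys	lambda_eV	assignment
696	0	0	bend
1704	1.594	0.337	C=N stretch
3446	0.029	0.013	C-H stretch
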