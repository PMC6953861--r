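# synthetic per-atom partial charges for the HCN-like fixture (H, C, N)
charge
0.23
0.08
-0.31
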