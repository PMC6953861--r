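{"state_label":"neutral","charge":0,"elements":["H","C","N"],"masses_amu":[1.00783,12,14.00307],"geometry_angstrom":[0,0,0,0,0,1.07,0,0,2.22],"frequencies_cm1":[778,778,2149,3500],"modes_massweighted":[[0.852713982804936,0,0,0],[0,0.852713982804936,0,0],[0,0,0.540294058526963,0.819005711985908],[-0.477047403718276,0,0,0],[0,-0.477047403718276,0,0],[0,0,0.540294058526963,-0.513631421682398],[0.212848862187695,0,0,0],[0,0.212848862187695,0,0],[0,0,-0.645108254978128,0.255758492322298]],"linear":true}
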