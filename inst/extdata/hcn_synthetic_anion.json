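{"state_label":"anion","charge":-1,"elements":["H","C","N"],"masses_amu":[1.00783,12,14.00307],"geometry_angstrom":[0,0,-0.05,0,0,1.09,0,0,2.29],"frequencies_cm1":[696,696,1704,3446],"modes_massweighted":[[0.849930034107221,0,0,0],[0,0.849930034107221,0,0],[0,0,0.540294058526963,0.819005711985908],[-0.480309089575475,0,0,0],[0,-0.480309089575475,0,0],[0,0,0.540294058526963,-0.513631421682398],[0.216615132420791,0,0,0],[0,0.216615132420791,0,0],[0,0,-0.645108254978128,0.255758492322298]],"linear":true}
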