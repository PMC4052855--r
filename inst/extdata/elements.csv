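# symbol, atomic number, atomic mass (g/mol), K-shell binding energy (eV),
# K-hole Auger lifetime (fs, NA when not bundled)
symbol,z,mass_g_mol,e_k_ev,tau_auger_fs
H,1,1.008,13.6,NA
C,6,12.011,284.2,10.0
N,7,14.007,409.9,7.1
O,8,15.999,543.1,5.0
Mg,12,24.305,1303.0,NA
P,15,30.974,2145.5,NA
S,16,32.06,2472.0,1.3
Ca,20,40.078,4038.5,NA
Mn,25,54.938,6539.0,0.62
Fe,26,55.845,7112.0,0.55
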