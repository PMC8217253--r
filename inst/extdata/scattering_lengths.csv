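# Bound coherent neutron scattering lengths, b (fm), and standard atomic
# masses (g/mol). Values from the standard tabulation of neutron scattering
# lengths and cross sections (Sears, Neutron News 3(3), 26-37, 1992).
# D is the 2H isotope; H is 1H.
element,mass,b_fm
H,1.008,-3.7390
D,2.01410,6.671
C,12.011,6.6460
N,14.007,9.36
O,15.999,5.803
F,18.998,5.654
Na,22.990,3.63
Mg,24.305,5.375
Si,28.086,4.1491
P,30.974,5.13
S,32.06,2.847
Cl,35.453,9.5770
K,39.098,3.67
Ca,40.078,4.70
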