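# solute: baricitinib
# cosolvent: DMSO
# antisolvent: water
# pressure_MPa: 0.1
# provenance: published mole-fraction solubility table, verbatim values
mass_fraction_cosolvent,temperature_K,x_exp,sd
0.0,298.2,2.23e-5,0.02e-5
0.0,303.2,3.90e-5,0.03e-5
0.0,308.2,5.61e-5,0.03e-5
0.0,313.2,8.02e-5,0.03e-5
0.0,323.2,1.71e-4,0.01e-4
0.1,298.2,4.66e-5,0.04e-5
0.1,303.2,7.99e-5,0.05e-5
0.1,308.2,1.17e-4,0.03e-4
0.1,313.2,1.65e-4,0.03e-4
0.1,323.2,3.57e-4,0.04e-4
0.2,298.2,9.29e-5,0.05e-5
0.2,303.2,1.65e-4,0.01e-4
0.2,308.2,2.36e-4,0.02e-4
0.2,313.2,3.36e-4,0.03e-4
0.2,323.2,7.05e-5,0.05e-5
0.3,298.2,1.99e-4,0.03e-4
0.3,303.2,3.34e-4,0.04e-4
0.3,308.2,4.79e-4,0.05e-4
0.3,313.2,6.83e-4,0.06e-4
0.3,323.2,1.42e-3,0.06e-3
0.4,298.2,4.09e-4,0.01e-4
0.4,303.2,6.77e-4,0.02e-4
0.4,308.2,9.72e-4,0.04e-4
0.4,313.2,1.41e-3,0.03e-3
0.4,323.2,2.79e-3,0.04e-3
0.5,298.2,8.43e-4,0.06e-4
0.5,303.2,1.41e-3,0.07e-3
0.5,308.2,2.00e-3,0.08e-3
0.5,313.2,2.83e-3,0.07e-3
0.5,323.2,5.52e-3,0.08e-3
0.6,298.2,1.76e-3,0.07e-3
0.6,303.2,2.83e-3,0.07e-3
0.6,308.2,4.07e-3,0.08e-3
0.6,313.2,5.75e-3,0.08e-3
0.6,323.2,1.10e-2,0.09e-2
0.7,298.2,3.60e-3,0.06e-3
0.7,303.2,5.78e-3,0.07e-3
0.7,308.2,8.25e-3,0.07e-3
0.7,313.2,1.19e-2,0.08e-2
0.7,323.2,2.18e-2,0.08e-2
0.8,298.2,7.42e-3,0.04e-3
0.8,303.2,1.18e-2,0.03e-2
0.8,308.2,1.69e-2,0.05e-2
0.8,313.2,2.40e-2,0.05e-2
0.8,323.2,4.32e-2,0.06e-2
0.9,298.2,1.55e-2,0.01e-2
0.9,303.2,2.40e-2,0.03e-2
0.9,308.2,3.44e-2,0.03e-2
0.9,313.2,4.86e-2,0.04e-2
0.9,323.2,8.53e-2,0.04e-2
1.0,298.2,3.15e-2,0.02e-2
1.0,303.2,4.86e-2,0.04e-2
1.0,308.2,6.96e-2,0.05e-2
1.0,313.2,9.85e-2,0.05e-2
1.0,323.2,1.69e-1,0.01e-1
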