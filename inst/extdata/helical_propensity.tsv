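# Helical propensity in [0,1]: Chou-Fasman alpha-helix propensities (P_alpha)
# min-max normalized over the 20 standard residues (G,P -> 0; E -> 1).
# Coil propensity, used by the backbone term, is 1 - helical.
residue	helical
A	0.9043
C	0.1383
D	0.4681
E	1.0000
F	0.5957
G	0.0000
H	0.4574
I	0.5426
K	0.6277
L	0.6809
M	0.9362
N	0.1064
P	0.0000
Q	0.5745
R	0.4362
S	0.2128
T	0.2766
V	0.5213
W	0.5426
Y	0.1277
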