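# Default rotamer probabilities for the side-chain propensity term.
# SYNTHETIC PLACEHOLDER: p_r is set equal to p_0 so the term is zero, as in
# the published model (its weight is 0); real values come from
# backbone-dependent rotamer-library statistics in the beta-strand basin
# and should be supplied by the user to activate the term.
residue	p_r	p_0
A	1.00	1.00
C	0.50	0.50
D	0.45	0.45
E	0.40	0.40
F	0.55	0.55
G	1.00	1.00
H	0.45	0.45
I	0.60	0.60
K	0.35	0.35
L	0.60	0.60
M	0.40	0.40
N	0.45	0.45
P	0.80	0.80
Q	0.40	0.40
R	0.35	0.35
S	0.55	0.55
T	0.60	0.60
V	0.70	0.70
W	0.50	0.50
Y	0.55	0.55
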