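aa	three	mass	sigma	charge	lambda_kr	lambda_urry
A	ALA	71.08	5.04	0	0.730	0.602941
R	ARG	156.19	6.56	1	0.000	0.558824
N	ASN	114.10	5.68	0	0.432	0.588235
D	ASP	115.09	5.58	-1	0.378	0.294118
C	CYS	103.14	5.48	0	0.595	0.647059
Q	GLN	128.13	6.02	0	0.514	0.558824
E	GLU	129.11	5.92	-1	0.459	0.000000
G	GLY	57.05	4.50	0	0.649	0.573529
H	HIS	137.14	6.08	0	0.514	0.764706
I	ILE	113.16	6.18	0	0.973	0.705882
L	LEU	113.16	6.18	0	0.973	0.720588
K	LYS	128.17	6.36	1	0.514	0.382353
M	MET	131.19	6.18	0	0.838	0.676471
F	PHE	147.18	6.36	0	1.000	0.823529
P	PRO	97.12	5.56	0	1.000	0.758824
S	SER	87.08	5.18	0	0.595	0.588235
T	THR	101.10	5.62	0	0.676	0.588235
W	TRP	186.21	6.78	0	0.946	1.000000
Y	TYR	163.18	6.46	0	0.865	0.897059
V	VAL	99.07	5.86	0	0.892	0.664706
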