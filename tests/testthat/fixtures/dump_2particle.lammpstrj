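ITEM: TIMESTEP
0
ITEM: NUMBER OF ATOMS
2
ITEM: BOX BOUNDS pp pp pp
-10.0 15.0
0.0 30.0
-5.0 5.0
ITEM: ATOMS id type x y z
1 1 1.5 2.5 -1.0
2 2 10.0 20.0 3.0
ITEM: TIMESTEP
100
ITEM: NUMBER OF ATOMS
2
ITEM: BOX BOUNDS pp pp pp
-10.0 15.0
0.0 30.0
-5.0 5.0
ITEM: ATOMS id type x y z
2 2 11.0 21.0 3.5
1 1 2.0 3.0 -0.5
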