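# Land-border contiguity among the 21 studied French departments.
# Hand-encoded from shared department borders; departments in different
# study regions are linked only where they truly share a border.
# A single token declares an isolated department (Rhone, 69, borders no
# other studied department).
# Lorraine (NE)
54 55
54 57
54 88
55 88
# Bretagne (NW)
22 29
22 35
22 56
29 56
35 56
# Auvergne (C)
03 63
43 63
15 43
15 63
# Auvergne - Midi-Pyrenees shared borders
12 15
15 46
# Midi-Pyrenees (SW)
12 46
46 82
12 81
12 82
31 82
32 82
81 82
31 81
31 32
32 65
09 31
31 65
# Rhone (SE), isolated
69
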