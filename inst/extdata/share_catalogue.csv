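label,s_ab,s_bc,s_ac,s_abc
lorraine_2008,0.46,0.23,0.20,0.12
lorraine_2008_alt,0.46,0.20,0.23,0.12
haute_garonne_2005,0.25,0.28,0.42,0.17
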