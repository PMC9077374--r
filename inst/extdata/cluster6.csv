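# energy_eV=100 mode=fixture
species,x,y,z
A,0,0,0
A,1.2,0.8,-0.5
A,-0.9,1.1,0.6
B,0.6,-0.7,0.9
B,-1.1,-0.4,-0.8
B,0.3,1.5,1.0
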