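((((Dsim:0.25,Dsec:0.25):2.75,Dmel:3):7,(Dsan:6,Dere:6):4):5,Dsuz:15);
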