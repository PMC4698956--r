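grade,selfreport_no,selfreport_yes
none,157,22
mild,59,11
modsev,15,13
PR,4,4
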