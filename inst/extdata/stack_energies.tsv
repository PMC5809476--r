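pair	energy
AT	-1.1
TA	-1.3
CG	-3.3
GC	-3.4
GT	-0.6
TG	-0.5
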