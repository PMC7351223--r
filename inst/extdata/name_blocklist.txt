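R-group
r-group
polymer
Polymer
Se1
As1
Si1
(C2H4O)n
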