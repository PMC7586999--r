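A	0.45000000	0.03333333	0.03333333	0.45000000	0.05000000	0.25000000	0.25000000	0.25000000	0.25000000	0.25000000	0.90000000	0.03333333	0.03333333
C	0.05000000	0.03333333	0.90000000	0.05000000	0.45000000	0.25000000	0.25000000	0.25000000	0.25000000	0.25000000	0.03333333	0.90000000	0.03333333
G	0.45000000	0.03333333	0.03333333	0.45000000	0.05000000	0.25000000	0.25000000	0.25000000	0.25000000	0.25000000	0.03333333	0.03333333	0.90000000
T	0.05000000	0.90000000	0.03333333	0.05000000	0.45000000	0.25000000	0.25000000	0.25000000	0.25000000	0.25000000	0.03333333	0.03333333	0.03333333
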