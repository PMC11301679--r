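>MT2_LIKE_SYNTHETIC synthetic metallothionein-2-like test protein (61 aa, 20 Cys); not a real MT2 sequence
MDPNCSCAAGDSCTCAGSCKCKECKCTSCKKSCCSCCPVGCAKCAQGCICKGASDKCSCCA
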