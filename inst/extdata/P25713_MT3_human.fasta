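>MT3_HUMAN_P25713 Metallothionein-3, Homo sapiens (68 aa, 20 Cys)
MDPETCPCPSGGSCTCADSCKCEGCKCTSCKKSCCSCCPAECEKCAKDCVCKGGEAAEAEAEKCSCCQ
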