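TOX
PDCD1
CTLA4
LAG3
HAVCR2
TIGIT
ENTPD1
CD160
CD244
BATF
EOMES
IRF4
NR4A1
NR4A2
TNFRSF9
CD38
VSIR
BTLA
PRDM1
IKZF2
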