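# Paddle-shaped phycobilisome composition schema.
# Core: 72 allophycocyanin alpha-beta protomer equivalents (the two ApcE
#   chromophorylated domains each count as one alpha-equivalent, paired with
#   an ApcB beta; the ApcE polypeptide itself is tallied on its linker row).
# Periphery: 12 phycocyanin hexamers of 6 protomers, 1 bilin on alpha and 2
#   on beta. The four distal chain hexamers are included here even though
#   deposited coordinate models omit them as too dynamic to build.
# Linkers carry no bilins of their own in this accounting. The CpcD copy
#   number is not established; 2 is a placeholder, so the polypeptide total
#   (310) is schema-dependent rather than a fixed constant.
name	compartment	copies	protomers_per_copy	chromophores_per_alpha	chromophores_per_beta	extra_chromophores	polypeptides_per_copy
apc_protomer	core	70	1	1	1	0	2
apcE_protomer_equiv	core	2	1	1	1	0	1
pc_hexamer	periphery	12	6	1	2	0	12
cpcN_linker	linker	2	0	0	0	0	1
cpcJ_linker	linker	2	0	0	0	0	1
cpcG_linker	linker	2	0	0	0	0	1
apcC_linker	linker	12	0	0	0	0	1
apcH_linker	linker	2	0	0	0	0	1
apcE_linker	linker	2	0	0	0	0	1
cpcD_linker	linker	2	0	0	0	0	1
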