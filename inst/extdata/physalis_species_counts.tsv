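species	n_sequences
P. angulate	7
P. hederaefolia var. puberula	1
P. angulatta var. villosa	4
P. heterophylla	1
P. acutifolia	1
P. lanceolata	1
P. crassifolia	2
P. longifolia	2
P. lagascae	1
P. peruviana	2
P. microcarpa	1
P. pumila	1
P. philadelphica	1
P. sordida	1
P. campanulata	1
P. virginiana	2
P. glutinosa	1
P. minimaculata	2
P. carpenteri	2
P. angustifolia	1
P. chenipodifolia	1
P. cinerascens	2
P. coztomatl	2
P. mollis	1
P. greenmanii	1
P. viscosa	1
P. hintonii	2
P. minima	6
P. pubescens	9
P. lassa	1
P. angustiphysa	1
P. arenicola	2
P. cordata	1
P. alkekengi var. franchetii	7
P. pruinosa	1
P. alkekengi	3
P. ignota	1
P. arborescens	2
P. nicandroides	1
P. melanocystis	1
P. patula	1
P. walteri	1
P. caudella	1
P. microphysa	1
P. hederaefolia	1
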