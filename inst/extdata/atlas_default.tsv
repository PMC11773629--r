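hemisphere	roi	x	y	z
left	precentral	-42	-8	48
left	postcentral	-44	-22	46
left	superior_temporal	-56	-20	4
left	middle_temporal	-58	-34	-4
left	inferior_temporal	-52	-46	-18
left	inferior_frontal	-50	22	12
left	middle_frontal	-40	28	34
left	superior_frontal	-22	20	52
left	supramarginal	-56	-40	32
left	angular	-46	-60	34
left	insula	-38	2	2
left	occipital	-24	-88	8
right	precentral	42	-8	48
right	postcentral	44	-22	46
right	superior_temporal	56	-20	4
right	middle_temporal	58	-34	-4
right	inferior_temporal	52	-46	-18
right	inferior_frontal	50	22	12
right	middle_frontal	40	28	34
right	superior_frontal	22	20	52
right	supramarginal	56	-40	32
right	angular	46	-60	34
right	insula	38	2	2
right	occipital	24	-88	8
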