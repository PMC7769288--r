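label_id	region_name	family
1	R.frontal	lobar16
2	L.frontal	lobar16
3	R.temporal	lobar16
4	L.temporal	lobar16
5	R.parietal	lobar16
6	L.parietal	lobar16
7	R.occipital	lobar16
8	L.occipital	lobar16
9	R.limbic	lobar16
10	L.limbic	lobar16
11	R.sublobar	lobar16
12	L.sublobar	lobar16
13	R.brainstem	lobar16
14	L.brainstem	lobar16
15	R.cerebellum	lobar16
16	L.cerebellum	lobar16
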