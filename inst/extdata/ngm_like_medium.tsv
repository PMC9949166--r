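compound_id	availability
glc__D	5
ser__L	1.5
thr__L	1.2
gly	1.0
ala__L	1.3
glu__L	1.8
asp__L	1.1
leu__L	0.9
ile__L	0.7
val__L	0.8
lys__L	0.9
arg__L	0.7
his__L	0.3
pro__L	1.0
mnl	0.5
tre	0.4
glyc3p	0.3
4hbz	0.2
gabab	0.3
ptrc	0.2
ac	2.0
cit	0.8
succ	0.6
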