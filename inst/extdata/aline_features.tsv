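# ALINE segment feature values, version 1.
# place: bilabial 1.0, labiodental .95, dental .9, alveolar .85, retroflex .8,
#   palato-alveolar .75, palatal .7, velar .6, uvular .5, pharyngeal .3,
#   glottal .1; vowels carry the place of their articulatory region.
# manner: stop 1.0, affricate .9, fricative .8, approximant .6,
#   high vowel .4, mid vowel .2, low vowel 0.
# high/back graded in [0,1]; remaining features binary.
segment	class	place	manner	voice	syllabic	nasal	retroflex	lateral	aspirated	long	high	back	round
p	C	1.0	1.0	0	0	0	0	0	0	0	0	0	0
b	C	1.0	1.0	1	0	0	0	0	0	0	0	0	0
t	C	0.85	1.0	0	0	0	0	0	0	0	0	0	0
d	C	0.85	1.0	1	0	0	0	0	0	0	0	0	0
k	C	0.6	1.0	0	0	0	0	0	0	0	0	0	0
g	C	0.6	1.0	1	0	0	0	0	0	0	0	0	0
m	C	1.0	1.0	1	0	1	0	0	0	0	0	0	0
n	C	0.85	1.0	1	0	1	0	0	0	0	0	0	0
ŋ	C	0.6	1.0	1	0	1	0	0	0	0	0	0	0
f	C	0.95	0.8	0	0	0	0	0	0	0	0	0	0
v	C	0.95	0.8	1	0	0	0	0	0	0	0	0	0
θ	C	0.9	0.8	0	0	0	0	0	0	0	0	0	0
ð	C	0.9	0.8	1	0	0	0	0	0	0	0	0	0
s	C	0.85	0.8	0	0	0	0	0	0	0	0	0	0
z	C	0.85	0.8	1	0	0	0	0	0	0	0	0	0
ʃ	C	0.75	0.8	0	0	0	0	0	0	0	0	0	0
ʒ	C	0.75	0.8	1	0	0	0	0	0	0	0	0	0
ʧ	C	0.75	0.9	0	0	0	0	0	0	0	0	0	0
ʤ	C	0.75	0.9	1	0	0	0	0	0	0	0	0	0
x	C	0.6	0.8	0	0	0	0	0	0	0	0	0	0
h	C	0.1	0.8	0	0	0	0	0	0	0	0	0	0
l	C	0.85	0.6	1	0	0	0	1	0	0	0	0	0
r	C	0.85	0.6	1	0	0	1	0	0	0	0	0	0
w	C	0.6	0.6	1	0	0	0	0	0	0	1	0	1
j	C	0.7	0.6	1	0	0	0	0	0	0	1	1	0
i	V	0.7	0.4	1	1	0	0	0	0	0	1	1	0
ɪ	V	0.7	0.4	1	1	0	0	0	0	0	0.8	1	0
y	V	0.7	0.4	1	1	0	0	0	0	0	1	1	1
e	V	0.7	0.2	1	1	0	0	0	0	0	0.5	1	0
ɛ	V	0.7	0.2	1	1	0	0	0	0	0	0.35	1	0
æ	V	0.7	0	1	1	0	0	0	0	0	0.1	1	0
a	V	0.65	0	1	1	0	0	0	0	0	0	0.5	0
ʌ	V	0.65	0.2	1	1	0	0	0	0	0	0.35	0.5	0
ə	V	0.65	0.2	1	1	0	0	0	0	0	0.5	0.5	0
ɜ	V	0.65	0.2	1	1	0	0	0	0	1	0.5	0.5	0
ɑ	V	0.6	0	1	1	0	0	0	0	0	0	0	0
ɒ	V	0.6	0	1	1	0	0	0	0	0	0	0	1
ɔ	V	0.6	0.2	1	1	0	0	0	0	0	0.35	0	1
o	V	0.6	0.2	1	1	0	0	0	0	0	0.5	0	1
ʊ	V	0.6	0.4	1	1	0	0	0	0	0	0.8	0	1
u	V	0.6	0.4	1	1	0	0	0	0	0	1	0	1
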