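# Penn Treebank tag -> coarse tag
NN	noun
NNS	noun
NNP	noun
NNPS	noun
VB	verb
VBD	verb
VBG	verb
VBN	verb
VBP	verb
VBZ	verb
MD	verb
JJ	adjective
JJR	adjective
JJS	adjective
RB	adverb
RBR	adverb
RBS	adverb
PRP	pronoun
PRP$	pronoun
WP	pronoun
WP$	pronoun
UH	interjection
DT	other
IN	other
CC	other
CD	other
TO	other
EX	other
FW	other
LS	other
PDT	other
POS	other
RP	other
SYM	other
WDT	other
WRB	other
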