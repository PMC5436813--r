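base_tag	n_subcategories	gloss
N	18	nouns
ADJ	30	adjectives
WW	21	verbs
TW	11	quantifiers
VNW	188	pronouns
LID	9	articles
VZ	3	prepositions
VG	2	conjunctions
BW	1	adverbs
TSW	1	interjections
SPEC	35	special forms
LET	1	punctuation
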