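class_id	control	azoospermia	oligozoospermia
b2/b4 del	0	9	14
gr/gr del	20	14	18
b2/b3 del	24	8	8
b1/b3 del	2	0	5
AZFb del	0	1	0
RBMY1J del	0	0	1
AZFa del	0	2	0
AZFb + c del	0	7	0
b2/b4 dup	2	0	3
gr/gr dup	5	7	6
b2/b3 dup	1	3	1
b2/b3 trip	0	0	1
BPY2 partial dup-Type I	2	1	1
BPY2 partial dup-Type II	2	1	0
Type I + gr/gr dup	0	0	1
b2/b4 dup + gr/gr dup	0	0	2
RBMY1J dup	0	0	1
AZFa partial dup Type I	4	1	0
AZFa partial dup Type II	0	0	1
b2/b3 del + DAZ1/2 dup	2	3	8
b2/b3 del + gr/gr dup	6	2	6
b2/b3 del + gr/gr trip	2	0	5
two gr/gr dels + b2/b4 dup	2	3	0
gr/gr del + b2/b3 trip	2	0	1
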