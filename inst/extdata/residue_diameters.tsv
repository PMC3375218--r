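aa	diameter
A	5.531
C	5.918
D	5.964
E	6.418
F	7.131
G	4.86
H	6.639
I	6.828
K	6.854
L	6.828
M	6.776
N	6.018
P	5.993
Q	6.5
R	6.919
S	5.539
T	6.053
V	6.442
W	7.577
Y	7.177
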