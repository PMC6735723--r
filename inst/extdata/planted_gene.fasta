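>fix_planted_1
GGTACAAAATTTATTCACAGAGCTCCTGGATCTACT
>fix_planted_2
GGTACTAAATTTATTCACAGAGCTCCTGGATCTACT
>fix_planted_3
GGTACTAAATTTCTTCACAGAGCTCCTGGATCTACT
>fix_planted_4
GGTACTAAATTTCTTCACAGAGCTCCTGGATCTACT
>outgroup
GGTACTAAATTTCTTCACAGAGCCCCTGGATATACT
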