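model	D	Dcv	SEcv
0	1115	0.5963	0.0006
1	1096	0.5914	0.0006
2	1080	0.5869	0.0007
3	1064	0.5864	0.0007
4	1050	0.5813	0.0007
5	1038	0.5810	0.0008
6	1026	0.5812	0.0008
7	1018	0.5811	0.0008
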