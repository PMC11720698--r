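participant,age,S1,S2,S3,S4,S5,S6,S7,S8,S9,S10
P1,yr18,4,3,2,4,2,5,3,5,1,6
P2,yr18,5,4,5,5,4,5,3,5,4,5
P3,yr18,5,3,2,5,2,2,5,5,2,3
P4,yr18,4,3,3,3,1,1,4,5,4,5
P5,yr18,7,2,4,6,2,3,3,4,2,4
P6,yr18,7,5,1,6,2,5,5,5,3,7
P7,yr18,7,3,2,4,1,4,3,5,5,5
P8,yr18,5,4,4,3,3,1,3,4,4,6
P9,yr18,4,4,5,4,2,5,4,5,4,5
P10,yr18,6,3,3,5,2,2,4,5,4,7
P11,yr75,6,2,5,3,1,4,1,3,3,5
P12,yr75,6,1,2,5,3,4,4,1,1,4
P13,yr75,5,2,1,2,3,2,3,1,1,5
P14,yr75,4,3,4,5,2,5,5,3,3,7
P15,yr75,4,1,4,3,1,3,1,1,1,5
P16,yr75,6,3,4,6,2,4,4,1,2,3
P17,yr75,7,3,5,6,4,4,2,2,2,4
P18,yr75,7,5,5,2,2,5,4,4,3,5
P19,yr75,5,3,5,4,2,3,2,1,3,5
P20,yr75,6,1,1,5,2,3,1,1,3,4
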