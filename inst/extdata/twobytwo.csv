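participant,d1s1m1,d1s1m2,d1s2m1,d1s2m2,d2s1m1,d2s1m2,d2s2m1,d2s2m2
Participant 1,3,3,5,5,5,3,1,4
Participant 2,5,7,4,7,4,5,4,3
Participant 3,4,3,4,4,5,6,2,3
Participant 4,1,2,4,5,6,5,3,2
Participant 5,6,4,8,8,8,9,7,9
Participant 6,5,4,5,7,7,7,5,6
Participant 7,6,6,7,7,7,4,8,5
Participant 8,4,4,5,3,6,4,5,4
Participant 9,5,3,6,3,5,6,6,7
Participant 10,7,8,9,7,7,9,8,9
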