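participant,yr65_day1,yr65_day2,yr75_day1,yr75_day2
Participant 1,32,30,27,27
Participant 2,38,42,35,37
Participant 3,42,38,43,43
Participant 4,57,55,51,49
Participant 5,24,30,19,25
Participant 6,57,49,52,50
Participant 7,37,39,34,34
Participant 8,33,33,24,26
Participant 9,40,38,35,35
Participant 10,22,20,23,21
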