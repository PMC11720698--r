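participant,group,day1,day2
Participant 1,65yr,42,40
Participant 2,65yr,23,23
Participant 3,65yr,44,46
Participant 4,65yr,20,20
Participant 5,65yr,43,47
Participant 6,65yr,37,37
Participant 7,65yr,48,46
Participant 8,65yr,53,53
Participant 9,65yr,50,52
Participant 10,65yr,33,33
Participant 11,75yr,27,27
Participant 12,75yr,35,37
Participant 13,75yr,43,43
Participant 14,75yr,51,49
Participant 15,75yr,19,25
Participant 16,75yr,52,50
Participant 17,75yr,34,34
Participant 18,75yr,24,26
Participant 19,75yr,35,35
Participant 20,75yr,23,21
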