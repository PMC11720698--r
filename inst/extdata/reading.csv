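language,background,text,p1,p2,p3,p4,p5,p6,p7,p8,p9,p10,p11,p12
L1,Yes,t1,36,31,25,41,25,21,37,31,28,22,30,25
L1,Yes,t2,38,29,32,30,30,37,38,34,36,25,30,32
L1,Yes,t3,38,25,32,46,25,30,42,30,41,22,28,36
L1,Yes,t4,48,24,28,40,28,28,40,26,36,19,40,30
L1,Yes,t5,38,22,28,32,30,35,37,31,38,21,33,24
L1,No,t6,39,36,40,42,35,30,55,34,34,28,48,42
L1,No,t7,34,17,35,34,25,19,43,29,30,19,39,43
L1,No,t8,42,26,36,40,31,31,44,36,31,34,43,30
L1,No,t9,42,26,35,32,34,25,42,31,39,31,36,40
L1,No,t10,45,34,36,41,35,28,52,36,40,28,33,34
L2,Yes,t11,34,21,26,30,33,29,39,30,34,30,28,29
L2,Yes,t12,39,24,26,37,27,29,46,31,47,27,33,34
L2,Yes,t13,41,28,25,39,28,35,38,32,43,28,35,23
L2,Yes,t14,32,27,32,44,20,25,42,27,44,18,39,33
L2,Yes,t15,46,22,31,42,33,31,40,34,58,33,32,29
L2,No,t16,41,27,44,34,38,42,49,45,42,43,51,37
L2,No,t17,50,39,42,35,34,39,49,42,37,33,43,37
L2,No,t18,57,37,50,40,46,49,45,38,45,38,45,36
L2,No,t19,46,32,38,31,37,36,56,33,40,34,38,26
L2,No,t20,51,36,40,35,40,38,53,27,42,37,40,35
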