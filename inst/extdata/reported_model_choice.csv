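hypothesis,scenario,pp,ci_lo,ci_hi,outliers_p05,outliers_p01
hypothesis1,S1,74,72,79,1,2
hypothesis1,S2,51,48,54,6,0
hypothesis1,S3,43,40,45,2,3
hypothesis2,S4,52,46,53,0,4
hypothesis2,S5,57,55,64,2,2
hypothesis2,S6,81,75,82,1,2
hypothesis3,S7,88,82,91,1,2
hypothesis3,S8,57,54,64,2,2
hypothesis3,S9,38,32,40,2,2
hypothesis4,S10,75,71,79,2,2
hypothesis4,S11,46,42,48,3,4
hypothesis4,S12,58,57,60,3,2
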