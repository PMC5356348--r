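subject,group,age_years,sex,mmse,side,stroke_duration_months,fm_baseline
S1,stroke,79,M,29,right,143,55
S2,stroke,46,M,28,left,42,58
S3,stroke,55,M,28,right,72,53
S4,stroke,58,M,27,right,69,45
S5,stroke,72,M,26,left,105,52
S6,stroke,81,M,30,left,130,40
S7,stroke,57,M,26,left,70,63
S8,stroke,55,F,30,left,19,45
S9,stroke,67,F,29,right,109,40
S10,stroke,45,M,30,right,12,30
S11,stroke,59,M,29,right,24,53
S12,stroke,71,M,28,right,13,65
S13,stroke,71,M,30,left,118,41
S14,stroke,57,M,30,right,22,51
S15,stroke,73,M,29,left,105,55
S16,stroke,65,M,30,left,100,33
C1,control,47,M,30,right,NA,NA
C2,control,53,M,27,right,NA,NA
C3,control,44,M,29,right,NA,NA
C4,control,69,M,29,right,NA,NA
C5,control,49,F,30,right,NA,NA
C6,control,53,M,28,right,NA,NA
C7,control,62,F,30,right,NA,NA
C8,control,55,F,30,right,NA,NA
C9,control,70,F,29,right,NA,NA
C10,control,63,F,30,right,NA,NA
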