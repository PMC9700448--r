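id,description,station,server_delta,ward_beds_delta,aau_beds_delta,amau_beds_delta,admitting_team
0,Base model (no intervention),,0,0,0,0,FALSE
1,Add one clerk to registration,registration,1,0,0,0,FALSE
2,Add one nurse to triage,triage,1,0,0,0,FALSE
3,Add one physician to assessment,assessment,1,0,0,0,FALSE
4,Add one ED physician to referral to medicine,referral_to_medicine,1,0,0,0,FALSE
5,Add one physician to decision to admit,decision_to_admit,1,0,0,0,FALSE
6,Add two physicians to decision to admit,decision_to_admit,2,0,0,0,FALSE
7,Add one nursing assistant to room allocation,room_allocation,1,0,0,0,FALSE
8,Add one nursing assistant to physical transfer,physical_transfer,1,0,0,0,FALSE
9,Admitting team in the ED (pool referral and decision servers),,0,0,0,0,TRUE
10,Combined: scenarios 6 and 9,decision_to_admit,2,0,0,0,TRUE
a,Add 31 inpatient ward beds,,0,31,0,0,FALSE
b,Add 22 ward beds plus admitting team,,0,22,0,0,TRUE
c,Add 14 ward beds plus two decision physicians,decision_to_admit,2,14,0,0,FALSE
d,Add 10 ward beds plus admitting team plus two decision physicians,decision_to_admit,2,10,0,0,TRUE
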