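# Clinical and demographic variables of the published 12-patient thalamic
# responsive-neurostimulation cohort (one row per patient). Transcribed
# values; ages in years, follow-up in months, Engel class as reported.
case,age_years,sex,seizure_type,epilepsy_duration_years,followup_months,prior_resection,rns_target,laterality,cortical_target,engel
1,35,F,GTC,25,79,no,ANT,R,R SMA,IA
2,48,M,GTC,24,43,no,ANT,B,,IA
3,18,F,"Absence, FTBTC",13,38,no,ANT,B,,IIB
4,34,F,"FIA, FTBTC",14,31,no,CM,B,,IVA
5,20,M,"Absence, FTBTC",16.75,38,yes,CM,B,,IVC
6,16,M,FTBTC,10,35,no,ANT,B,,IVA
7,22,M,FIA,6,29,no,CM,B,,IIIA
8,18,M,GTC,3.83,67,no,CM,B,,IIIA
9,25,M,FTBTC,8,39,no,CM,B,,IA
10,22,F,FTBTC,11,31,no,CM,B,,IIB
11,31,F,GTC,28,16,no,CM,B,,IIIA
12,28,F,FTBTC,7,20,no,ANT,L,L hippocampus,IVB
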