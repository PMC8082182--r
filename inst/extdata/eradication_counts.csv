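site,organism,n,eradicated
Bloodstream,SA,8,8
Bloodstream,CoNS,32,31
Bloodstream,Enterococcus,7,7
Bloodstream,Other,4,4
Pulmonary,SA,24,23
Pulmonary,CoNS,1,1
Pulmonary,Enterococcus,1,1
Pulmonary,Other,3,3
Urinary tract,SA,2,2
Urinary tract,CoNS,2,2
Urinary tract,Enterococcus,11,11
Central nervous system,SA,1,0
Central nervous system,CoNS,2,2
Central nervous system,Enterococcus,2,2
Central nervous system,Other,6,6
Endocarditis,SA,1,1
Endocarditis,CoNS,1,1
Endocarditis,Enterococcus,1,1
Endocarditis,Other,3,3
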