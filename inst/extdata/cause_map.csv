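icd_low,icd_high,intermediate,broad
A15,A19,tuberculosis,communicable
B20,B24,hiv_aids,communicable
J09,J22,respiratory_infection,communicable
A00,B99,other_communicable,communicable
G00,G09,other_communicable,communicable
C00,D48,neoplasm,noncommunicable
E10,E14,diabetes,noncommunicable
I00,I99,cardiovascular,noncommunicable
X40,X44,drug_overdose,noncommunicable
V01,V99,transport_injury,transport
X60,X84,suicide,suicide
X85,Y09,interpersonal_violence,violence
Y20,Y20,undetermined_hanging,other_unknown
Y10,Y34,undetermined_intent,other_unknown
Y35,Y98,other_injury,other_unknown
W00,X59,other_injury,other_unknown
R00,R99,ill_defined,other_unknown
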