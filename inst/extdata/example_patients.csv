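patient_id,disease,course,tgd_fraction_pbmc,Vd1,Vd2,Vg9,CD5,CD8,CD16,CD56,CD57,CD28,CD45RA,CD45RO,CD62L,neutropenia,anemia,autoimmune_disease,splenomegaly
pt_ex1,Tgd_LGLL,indolent,0.42,-,+,+,+,+,+,+,+,-,+,+,-,-,-,na,-
pt_ex2,Tgd_LGLL,symptomatic,0.65,+,-,-,-,+,+,-,+,-,+,-,-,+,+,+,-
pt_ex3,HSTCL,not_applicable,0.87,+,-,-,-,-,+,+,-,na,na,na,na,-,+,-,+
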