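age_group,region,value
children,northern,7.26e-8
children,central,2.24e-7
children,southern,9.21e-7
children,eastern,8.37e-9
children,taiwan,3.19e-7
working_age,northern,1.52e-7
working_age,central,4.44e-7
working_age,southern,1.56e-6
working_age,eastern,1.82e-8
working_age,taiwan,6e-7
older,northern,7.68e-8
older,central,2.27e-7
older,southern,2.79e-6
older,eastern,7.79e-9
older,taiwan,8.84e-7
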