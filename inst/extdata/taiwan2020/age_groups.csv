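id,min_age,max_age,label
children,0,14,Children (0-14)
working_age,15,64,Working-age adults (15-64)
older,65,NA,Older adults (65+)
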