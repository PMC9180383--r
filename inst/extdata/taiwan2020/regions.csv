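id,label,national,share
northern,Northern,FALSE,0.4448
central,Central,FALSE,0.2488
southern,Southern,FALSE,0.277
eastern,Eastern,FALSE,0.0246
taiwan,Taiwan,TRUE,NA
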