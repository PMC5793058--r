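"rt","mz","area","channel","condition"
17.2,NA,53,"radio","standard"
19.9,NA,47,"radio","standard"
6.9,353.2,5,"ms","EDTA"
8.5,351.2,4,"ms","EDTA"
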