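stage,n
suspected,55
screened,29
inclusion,17
enrolled,14
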