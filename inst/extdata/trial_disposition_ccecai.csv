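dog_id,group,phase,status,exclusion_reason
fmt1,FMT,treatment,relapsed,
fmt2,FMT,treatment,relapsed,
fmt3,FMT,treatment,responder,
fmt4,FMT,treatment,responder,
fmt5,FMT,treatment,responder,
fmt6,FMT,treatment,responder,
fmt7,FMT,treatment,responder,
fmt3,FMT,post_treatment,excluded,corticosteroids for skin condition
fmt4,FMT,post_treatment,relapsed,
fmt5,FMT,post_treatment,relapsed,
fmt6,FMT,post_treatment,responder,
fmt7,FMT,post_treatment,responder,
plc1,placebo,treatment,excluded,pyometra
plc2,placebo,treatment,relapsed,
plc3,placebo,treatment,relapsed,
plc4,placebo,treatment,relapsed,
plc5,placebo,treatment,responder,
plc6,placebo,treatment,responder,
plc7,placebo,treatment,responder,
plc5,placebo,post_treatment,responder,
plc6,placebo,post_treatment,responder,
plc7,placebo,post_treatment,responder,
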