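condition,weight,duration_years,lifelong
episode,0.133,0.022,FALSE
amputation,0.021,NA,TRUE
ptsd,0.158,1,FALSE
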