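period_start,period_end,field,citizen,simultaneous
2004,2013,405,0,0
2014,2024,930,335,98
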