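symbol	ref_length	tm_spans
SLC3A2	529	
SLC7A5	507	30-50;65-85;100-120;140-160;190-210;235-255;265-285;300-320;335-355;370-390;410-430;450-470
KEAP1	624	
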