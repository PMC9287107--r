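stage,count
Wake,2668
REM,2562
NREM,9434
Total,14666
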