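((t1:0.15,t2:0.25):0.1,(t3:0.2,t4:0.3):0.05);
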