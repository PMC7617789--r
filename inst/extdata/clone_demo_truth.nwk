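(((A1:1,A2:1)A:1,(B1:1)B:1)root:1);
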