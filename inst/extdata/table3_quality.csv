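quantity,IA1,IA2,IA3
snr,95.61,154.59,100.81
vnr,58.31,56.17,62.66
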