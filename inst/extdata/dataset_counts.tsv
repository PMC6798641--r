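dataset	positives	negatives
cross_species	1677	8266
human	863	7422
new	690	8246
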