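# Pooled population of the nine regions, 2018/19.
population_million
92.4
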