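sex	non_smoker	non_sustained	sustained	unknown
male	4460	476	1987	650
female	4272	486	1719	644
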