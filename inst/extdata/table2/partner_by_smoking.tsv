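partner_smoked	non_smoker	non_sustained	sustained
false	8125	863	3032
true	339	88	486
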