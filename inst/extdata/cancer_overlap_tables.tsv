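method	in_set_in_list	in_set_only	in_list_only	in_neither
proposed	10	19	732	17730
fu_et_al	3	55	739	17694
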