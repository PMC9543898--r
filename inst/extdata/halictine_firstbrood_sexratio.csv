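social_organization,female_bias,no_female_bias
primitively_eusocial,29,1
not_eusocial,6,11
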