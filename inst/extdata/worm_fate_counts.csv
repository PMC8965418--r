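treatment,source,recovered_total,unattached,in_donor_cup,in_experimental_cup,in_receiver_cup
intraspecific,alternative_sourced,158,38,33,3,2
interspecific,alternative_sourced,396,3,3,0,0
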