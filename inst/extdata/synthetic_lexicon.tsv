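lexicon	category_id	polarity	negation_variants	terms
fixlex	mood	negative	3	sad;tearful;hopeless;anxious;worried;distress
fixlex	kinship	neutral		mother;father;brother;sister;family;wife;husband;son;daughter
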