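word	parse
νιωθω	one
γυαλα	one
διαβατης	one
κλεψια	one
γεια	one
μια	one
πιο	one
ποιος	one
ποια	one
ποιο	one
γιος	one
γιατι	one
διακος	one
πιανω	one
χιονι	one
δουλεια	one
καρδια	one
παιδια	one
ματια	one
βιος	two
θεια	one
αδεια	one
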