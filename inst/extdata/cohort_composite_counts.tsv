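composite	control	spermatogenic_failure	azoospermia	oligozoospermia
any_cnv	76	145	62	82
any_deletion	60	115	49	65
any_duplication	16	30	13	17
any_duplication_azfc	12	27	12	15
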