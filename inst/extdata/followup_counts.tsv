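quantity	events	total
deaths_among_followed_cases	1994	5921
crc_deaths_among_deaths	1415	1994
recurrences_among_linked_cases	942	2045
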