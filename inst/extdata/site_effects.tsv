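site	from	to	delta_nm	provenance
114	A	S	5	package default magnitude: chosen so the joint A114S+A118S shift is ~10 nm and a single-site duplicate gap falls in 3-9 nm; override via a user effects table
118	A	S	5	A118S known to induce a +5 nm shift in SWS1 lambda-max (in-vitro mutagenesis literature)
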