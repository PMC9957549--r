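label,allele
CD99-H01,D1
CD99-H02,D2
CD99-H03,D3
CD99-H04,D3
CD99-H05,
CD99-H06,D3
CD99-H07,
CD99-H08,
CD99-H09,
CD99-H10,
CD99-H11,
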