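sample_id	date
s01	2005-05-15
s02	2005-07-15
s03	2005-09-15
s04	2005-11-15
s05	2006-01-15
s06	2006-03-15
s07	2006-05-15
s08	2006-07-15
s09	2006-09-15
s10	2006-11-15
s11	2007-01-15
s12	2007-03-15
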