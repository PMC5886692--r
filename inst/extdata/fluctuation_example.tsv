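culture_id	mutant_count	viable_cells
c01	40	2e+08
c02	5	2e+08
c03	13	2e+08
c04	119	2e+08
c05	3	2e+08
c06	1	2e+08
c07	7	2e+08
c08	7	2e+08
c09	9	2e+08
c10	19	2e+08
c11	8	2e+08
c12	7	2e+08
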