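channel	region
CH1	lFrontal
CH2	lFrontal
CH3	lTemporal
CH4	lFrontal
CH5	lFrontal
CH6	lTemporal
CH7	lTemporal
CH8	lIFG
CH9	lFrontal
CH10	lTemporal
CH11	lSTG
CH12	lTemporal
CH13	lIFG
CH14	lSTG
CH15	lTPJ
CH16	lFrontal
CH17	lIFG
CH18	lSTG
CH19	lTPJ
CH20	lParietal
CH21	lSTG
CH22	lParietal
CH23	rTPJ
CH24	rTPJ
CH25	rTPJ
CH26	rTPJ
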