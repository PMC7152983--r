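system	dE_mean	dE_sd	dVDW_mean	dVDW_sd	dLIPO_mean	dLIPO_sd	dGBELE_mean	dGBELE_sd
PPARalpha	-138.0	7.3	-82.9	3.8	-67.5	3.0	12.4	4.8
PPARbeta	-135.9	5.3	-76.4	2.9	-71.9	2.4	12.4	2.3
PPARgamma	-144.6	5.6	-87.9	3.0	-71.3	2.2	14.6	3.5
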