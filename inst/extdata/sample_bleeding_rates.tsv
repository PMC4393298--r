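control_organism	control_pct	protocol	multiplexed	observed	expected
yeast	61	standard	yes	3.5e-04	8.5e-07
yeast	20	long_template	yes	7.3e-05	8.5e-07
yeast	40	long_template	yes	1.2e-04	8.5e-07
yeast	60	long_template	yes	1.5e-04	8.5e-07
yeast	80	long_template	yes	1.9e-04	8.5e-07
yeast	90	long_template	yes	1.7e-04	8.5e-07
yeast	0	long_template	no	8.1e-07	8.5e-07
yeast	0	long_template	no	8.9e-07	8.5e-07
phix	50	standard	yes	1.5e-01	1.6e-07
phix	50	standard	yes	2.0e-01	1.6e-07
phix	0	long_template	no	0	1.6e-07
phix	0	long_template	no	0	1.6e-07
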