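study_id	scenario	species	time_h	value	unit_kind	normalization_ref_time	omit_flag	omit_reason
synthetic-hornig	constitutive	X	0	0	absolute	NA	FALSE	NA
synthetic-hornig	constitutive	X	3	1.1613571878165363	absolute	NA	TRUE	below assay limit of quantitation (synthetic emulation)
synthetic-hornig	constitutive	X	6	1.980082990970719	absolute	NA	FALSE	NA
synthetic-hornig	constitutive	X	12	3.4091381340408824	absolute	NA	FALSE	NA
synthetic-hornig	constitutive	X	24	5.8142451630966425	absolute	NA	FALSE	NA
synthetic-hornig	constitutive	X	48	6.549704557260594	absolute	NA	FALSE	NA
synthetic-hornig	constitutive	X	72	7.704346966657644	absolute	NA	FALSE	NA
synthetic-jung	pulse_chase	I	0	1	relative	0	FALSE	NA
synthetic-jung	pulse_chase	I	1	0.9861277727004482	relative	0	FALSE	NA
synthetic-jung	pulse_chase	I	2	0.9474524583516252	relative	0	FALSE	NA
synthetic-jung	pulse_chase	I	4	0.6030508994308859	relative	0	FALSE	NA
synthetic-jung	pulse_chase	I	8	0.176681789640952	relative	0	FALSE	NA
synthetic-jung	pulse_chase	X	0.5	0	relative	8	FALSE	NA
synthetic-jung	pulse_chase	X	1	0	relative	8	FALSE	NA
synthetic-jung	pulse_chase	X	2	0.05242649034585509	relative	8	FALSE	NA
synthetic-jung	pulse_chase	X	4	0.5216963222907717	relative	8	FALSE	NA
synthetic-jung	pulse_chase	X	6	0.8361236780931314	relative	8	FALSE	NA
synthetic-jung	pulse_chase	X	8	1	relative	8	FALSE	NA
synthetic-jung	pulse_chase	X	10	0.9956054727674574	relative	8	TRUE	trend inconsistent with remaining observations (synthetic emulation)
synthetic-kinghorn	constitutive	I	0	1	relative	0	FALSE	NA
synthetic-kinghorn	constitutive	I	8	0.9562686008460707	relative	0	FALSE	NA
synthetic-kinghorn	constitutive	I	24	1.0134876031248705	relative	0	FALSE	NA
synthetic-kinghorn	constitutive	X	2	0.1616366728368359	relative	24	FALSE	NA
synthetic-kinghorn	constitutive	X	4	0.2956523034391483	relative	24	FALSE	NA
synthetic-kinghorn	constitutive	X	8	0.5057958629301778	relative	24	FALSE	NA
synthetic-kinghorn	constitutive	X	12	0.689836046811948	relative	24	FALSE	NA
synthetic-kinghorn	constitutive	X	18	0.9142067185995862	relative	24	FALSE	NA
synthetic-kinghorn	constitutive	X	24	1	relative	24	FALSE	NA
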