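species_label	mz_printed	rt_standard_min	rt_retina_min	role
21:5 (IS)	315.233	NA	3.19	internal_standard
20:4	303.233	NA	3.3	marker
20:5	301.2173	NA	3.11	marker
22:4	331.2643	NA	3.58	marker
22:5 (1)	329.2486	NA	3.35	marker
22:5 (2)	329.2486	NA	3.44	marker
22:6	327.233	3.24	3.23	marker
24:4 (1)	359.2956	NA	3.91	marker
24:4 (2)	NA	NA	4.02	marker
24:5	357.2799	3.66	3.69	marker
24:6	355.2643	NA	3.45	marker
26:4	387.3269	NA	4.32	marker
26:5	385.3112	NA	4.03	marker
26:6	383.2956	NA	3.73	marker
28:4	415.3582	NA	4.76	marker
28:5	413.3425	NA	4.42	marker
28:6	411.3269	NA	4.12	marker
30:4	443.3895	NA	5.26	marker
30:5 (1)	441.3738	NA	4.89	marker
30:5 (2)	441.3738	NA	4.99	marker
30:6	439.3582	NA	NA	marker
32:4 (1)	471.4208	NA	5.76	marker
32:4 (2)	471.4208	NA	5.91	marker
32:5 (1)	469.4051	NA	5.34	marker
32:5 (2)	469.4051	NA	5.45	marker
32:6	467.3895	4.98	5.01	marker
34:4	499.4521	NA	6.28	marker
34:5	497.4364	5.88	5.89	marker
34:6	495.4208	5.42	5.46	marker
36:4	527.4834	NA	6.67	marker
36:5	525.4677	NA	6.34	marker
36:6	523.4521	NA	5.94	marker
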