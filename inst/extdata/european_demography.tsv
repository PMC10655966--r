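# Piecewise-constant single-population approximation of the European (CEU)
# demographic history of Tennessen et al. (2012) Science 337:64-69
# (generation time 25 years). Exponential-growth phases (1.95%/gen over the
# most recent ~205 generations; 0.307%/gen between ~205 and 920 generations)
# are discretized into geometric-mean steps of 10 and 12 epochs.
# Backward-time anchors: present Ne ~512,000; 9,476 at 204.6 gen; 1,032 at
# 920 gen; out-of-Africa bottleneck Ne 1,861 (920-2,040 gen); ancestral
# expansion Ne 14,474 (2,040-5,920 gen); ancestral Ne 7,310 beyond.
start_gen	ne
0	419397.1
20.462	281407.9
40.924	188819.7
61.387	126694.6
81.849	85009.8
102.311	57040.1
122.773	38272.9
143.235	25680.4
163.698	17231.1
184.16	11561.7
204.622	8647
264.237	7200.8
323.852	5996.5
383.466	4993.6
443.081	4158.4
502.696	3463
562.311	2883.8
621.926	2401.5
681.541	1999.8
741.156	1665.4
800.77	1386.9
860.385	1154.9
920	1861
2040	14474
5920	7310
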