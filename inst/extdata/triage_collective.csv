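# cardinality: 7
# q: 3
# experts: panel
# alternatives: P1; P2; P3; P4; P5
# criteria: severity; emergency; special; insurance
# criteriaTypes: benefit; benefit; benefit; benefit
"s1:0.3168|0.8796,0.2415","s2:-0.4661|0.8171,0.2991","s2:-0.3446|0.8326,0.2924","s2:-0.3901|0.8735,0.2093"
"s1:0.0381|0.8929,0.2348","s1:0.4579|0.8749,0.2295","s1:0.2364|0.9162,0.1942","s2:-0.3328|0.9185,0.3314"
"s1:0.3495|0.9011,0.1420","s1:0.0451|0.9455,0.2347","s2:-0.4277|0.8303,0.0867","s2:-0.4513|0.8946,0.0950"
"s1:0.0195|0.8822,0.2127","s1:0.3674|0.8965,0.1637","s2:-0.4036|0.8709,0.2378","s1:0.3364|0.8838,0.1307"
"s2:-0.3250|0.8453,0.2623","s1:0.2793|0.9129,0.1944","s1:0.0501|0.9153,0.1633","s2:-0.4619|0.9048,0.2460"
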