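# cardinality: 7
# q: 3
# experts: E1; E2; E3
# alternatives: P1; P2; P3; P4; P5
# criteria: severity; emergency; special; insurance
# criteriaTypes: benefit; benefit; benefit; benefit
"s2|0.6,0.3","s3|0.4,0.5","s5|0.5,0.4","s4|0.6,0.3"
"s1|0.5,0.4","s3|0.6,0.4","s2|0.7,0.3","s4|0.8,0.7"
"s2|0.7,0.1","s1|0.8,0.3","s4|0.4,0.1","s5|0.6,0.1"
"s1|0.3,0.4","s3|0.7,0.1","s4|0.5,0.5","s2|0.5,0.1"
"s4|0.5,0.4","s2|0.4,0.3","s1|0.6,0.2","s3|0.7,0.3"
"s5|0.6,0.5","s6|0.4,0.3","s2|0.5,0.5","s3|0.6,0.3"
"s4|0.5,0.4","s3|0.6,0.3","s1|0.7,0.3","s6|0.6,0.3"
"s5|0.6,0.4","s3|0.7,0.5","s6|0.9,0.1","s1|0.8,0.2"
"s2|0.4,0.3","s1|0.6,0.5","s3|0.7,0.2","s5|0.8,0.1"
"s5|0.5,0.3","s2|0.6,0.3","s6|0.8,0.1","s5|0.8,0.2"
"s1|0.5,0.4","s3|0.6,0.5","s4|0.7,0.1","s5|0.8,0.4"
"s2|0.6,0.1","s1|0.6,0.1","s3|0.5,0.4","s4|0.9,0.1"
"s4|0.7,0.4","s5|0.8,0.6","s1|0.1,0.2","s6|0.4,0.1"
"s5|0.8,0.3","s1|0.9,0.1","s2|0.6,0.2","s3|0.5,0.5"
"s6|0.8,0.5","s2|0.7,0.4","s1|0.6,0.5","s4|0.6,0.6"
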