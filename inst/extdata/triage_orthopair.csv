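mu1,nu1,mu2,nu2,mu3,nu3,mu4,nu4
0.8796,0.2415,0.8171,0.2991,0.8326,0.2924,0.8735,0.2093
0.8729,0.2348,0.8749,0.2295,0.9162,0.1942,0.9185,0.3314
0.9011,0.1420,0.9455,0.2347,0.8303,0.0876,0.8946,0.0951
0.8822,0.2127,0.8964,0.1647,0.8709,0.2378,0.8838,0.1307
0.8453,0.2623,0.9129,0.1944,0.9153,0.1633,0.9048,0.2460
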