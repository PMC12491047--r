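treatment,observed_kg_hm2,simulated_kg_hm2,re_printed_pct
CK,14545.68,14339.73,-1.42
T1,14383.15,13924.62,-3.19
T2,13807.71,12703.77,-8.00
T3,13251.24,13367.36,0.88
T4,12847.3,11450.82,-10.87
T5,12782.28,12947.36,1.29
T6,12183.15,11436.24,-6.13
T7,12437.72,11458.47,-7.87
T8,10843.33,9736.75,-10.21
2022QC,12266.04,12437.94,1.40
2023QC,13316.36,13746.3,3.23
2024QC,12266.04,11964.37,-2.46
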