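quota_mm,plan,unoptimized_yield_kg_hm2,optimized_yield_kg_hm2,unoptimized_wue,optimized_wue
507,CK,14339.73,15651.27,28.99,31.34
472,T1,13924.62,15328.70,30.47,33.87
437,T2,12703.77,13982.48,29.32,31.69
456,T3,13367.36,14608.87,27.59,30.30
404,T4,11450.82,12566.50,28.52,30.23
421,T5,12947.36,14182.96,25.85,28.19
369,T6,11436.24,12564.25,25.22,26.72
386,T7,11458.47,12586.35,26.62,28.74
334,T8,9736.75,10550.24,25.51,27.09
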