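"event","day","stage","depth_mm"
1,11,"initial",26.2410699924778
2,33,"initial",26.2410699924778
3,50,"rapid",75.7169579908857
4,64,"rapid",75.7169579908857
5,76,"rapid",75.7169579908857
6,90,"rapid",75.7169579908857
7,98,"mid",27.6931083570302
8,102,"mid",27.6931083570302
9,105,"mid",27.6931083570302
10,115,"late",55.8218442350485
11,131,"late",55.8218442350485
12,147,"late",55.8218442350485
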