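0.000 29.374 68.910 80.316 3.214 15.519 31.247 10.785 19.954 657.984
29.374 0.000 9.897 9.371 1.152 5.427 23.931 75.936 15.735 29.017
68.910 9.897 0.000 24.537 22.726 114.419 6.283 52.700 12.001 22.757
80.316 9.371 24.537 0.000 60.389 10.141 0.618 50.726 231.072 140.619
3.214 1.152 22.726 60.389 0.000 9.884 10.037 26.248 13.709 33.200
15.519 5.427 114.419 10.141 9.884 0.000 752.624 36.117 143.153 36.591
31.247 23.931 6.283 0.618 10.037 752.624 0.000 18.117 19.393 7.708
10.785 75.936 52.700 50.726 26.248 36.117 18.117 0.000 73.766 28.238
19.954 15.735 12.001 231.072 13.709 143.153 19.393 73.766 0.000 4.000
657.984 29.017 22.757 140.619 33.200 36.591 7.708 28.238 4.000 0.000
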