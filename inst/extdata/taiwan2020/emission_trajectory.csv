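region,period,path,grams
northern,2020,policy,5.7628
northern,2021-2025,policy,5.2826
northern,2026-2030,policy,4.8023
northern,2031-2035,policy,4.3221
northern,2036-2040,policy,3.8419
northern,2041-2045,policy,3.3616
northern,2046-2050,policy,2.8814
northern,2051-2055,policy,2.3051
northern,2056-2060,policy,1.7288
northern,2061-2065,policy,1.1526
northern,2066-2070,policy,0.5763
northern,2020,baseline,5.7628
northern,2021-2025,baseline,5.7628
northern,2026-2030,baseline,5.7628
northern,2031-2035,baseline,5.7628
northern,2036-2040,baseline,5.7628
northern,2041-2045,baseline,5.7628
northern,2046-2050,baseline,5.7628
northern,2051-2055,baseline,5.7628
northern,2056-2060,baseline,5.7628
northern,2061-2065,baseline,5.7628
northern,2066-2070,baseline,5.7628
central,2020,policy,19.3798
central,2021-2025,policy,17.7648
central,2026-2030,policy,16.1498
central,2031-2035,policy,14.5348
central,2036-2040,policy,12.9198
central,2041-2045,policy,11.3049
central,2046-2050,policy,9.6899
central,2051-2055,policy,7.7519
central,2056-2060,policy,5.8139
central,2061-2065,policy,3.876
central,2066-2070,policy,1.938
central,2020,baseline,19.3798
central,2021-2025,baseline,19.3798
central,2026-2030,baseline,19.3798
central,2031-2035,baseline,19.3798
central,2036-2040,baseline,19.3798
central,2041-2045,baseline,19.3798
central,2046-2050,baseline,19.3798
central,2051-2055,baseline,19.3798
central,2056-2060,baseline,19.3798
central,2061-2065,baseline,19.3798
central,2066-2070,baseline,19.3798
southern,2020,policy,31.9743
southern,2021-2025,policy,29.3097
southern,2026-2030,policy,26.6452
southern,2031-2035,policy,23.9807
southern,2036-2040,policy,21.3162
southern,2041-2045,policy,18.6517
southern,2046-2050,policy,15.9871
southern,2051-2055,policy,12.7897
southern,2056-2060,policy,9.5923
southern,2061-2065,policy,6.3949
southern,2066-2070,policy,3.1974
southern,2020,baseline,31.9743
southern,2021-2025,baseline,31.9743
southern,2026-2030,baseline,31.9743
southern,2031-2035,baseline,31.9743
southern,2036-2040,baseline,31.9743
southern,2041-2045,baseline,31.9743
southern,2046-2050,baseline,31.9743
southern,2051-2055,baseline,31.9743
southern,2056-2060,baseline,31.9743
southern,2061-2065,baseline,31.9743
southern,2066-2070,baseline,31.9743
eastern,2020,policy,0.6832
eastern,2021-2025,policy,0.6262
eastern,2026-2030,policy,0.5693
eastern,2031-2035,policy,0.5124
eastern,2036-2040,policy,0.4554
eastern,2041-2045,policy,0.3985
eastern,2046-2050,policy,0.3416
eastern,2051-2055,policy,0.2733
eastern,2056-2060,policy,0.205
eastern,2061-2065,policy,0.1366
eastern,2066-2070,policy,0.0683
eastern,2020,baseline,0.6832
eastern,2021-2025,baseline,0.6832
eastern,2026-2030,baseline,0.6832
eastern,2031-2035,baseline,0.6832
eastern,2036-2040,baseline,0.6832
eastern,2041-2045,baseline,0.6832
eastern,2046-2050,baseline,0.6832
eastern,2051-2055,baseline,0.6832
eastern,2056-2060,baseline,0.6832
eastern,2061-2065,baseline,0.6832
eastern,2066-2070,baseline,0.6832
taiwan,2020,policy,57.8
taiwan,2021-2025,policy,52.9833
taiwan,2026-2030,policy,48.1667
taiwan,2031-2035,policy,43.35
taiwan,2036-2040,policy,38.5333
taiwan,2041-2045,policy,33.7167
taiwan,2046-2050,policy,28.9
taiwan,2051-2055,policy,23.12
taiwan,2056-2060,policy,17.34
taiwan,2061-2065,policy,11.56
taiwan,2066-2070,policy,5.78
taiwan,2020,baseline,57.8
taiwan,2021-2025,baseline,57.8
taiwan,2026-2030,baseline,57.8
taiwan,2031-2035,baseline,57.8
taiwan,2036-2040,baseline,57.8
taiwan,2041-2045,baseline,57.8
taiwan,2046-2050,baseline,57.8
taiwan,2051-2055,baseline,57.8
taiwan,2056-2060,baseline,57.8
taiwan,2061-2065,baseline,57.8
taiwan,2066-2070,baseline,57.8
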