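age_group,region,period,value
children,northern,2020,1318119
children,northern,2021-2025,1264892
children,northern,2026-2030,1192701
children,northern,2031-2035,1124171
children,northern,2036-2040,1132252
children,northern,2041-2045,1113024
children,northern,2046-2050,1064712
children,northern,2051-2055,1001184
children,northern,2056-2060,943498
children,northern,2061-2065,899735
children,northern,2066-2070,871704
working_age,northern,2020,7477322
working_age,northern,2021-2025,7267601
working_age,northern,2026-2030,6877924
working_age,northern,2031-2035,6504056
working_age,northern,2036-2040,6081763
working_age,northern,2041-2045,5624320
working_age,northern,2046-2050,5156703
working_age,northern,2051-2055,4821029
working_age,northern,2056-2060,4488235
working_age,northern,2061-2065,4156714
working_age,northern,2066-2070,3911141
older,northern,2020,1684598
older,northern,2021-2025,1922894
older,northern,2026-2030,2326148
older,northern,2031-2035,2665299
older,northern,2036-2040,2908197
older,northern,2041-2045,3120420
older,northern,2046-2050,3290247
older,northern,2051-2055,3287280
older,northern,2056-2060,3246798
older,northern,2061-2065,3183865
older,northern,2066-2070,3021274
children,central,2020,737293
children,central,2021-2025,707520
children,central,2026-2030,667140
children,central,2031-2035,628808
children,central,2036-2040,633328
children,central,2041-2045,622573
children,central,2046-2050,595549
children,central,2051-2055,560015
children,central,2056-2060,527748
children,central,2061-2065,503269
children,central,2066-2070,487590
working_age,central,2020,4182459
working_age,central,2021-2025,4065151
working_age,central,2026-2030,3847184
working_age,central,2031-2035,3638060
working_age,central,2036-2040,3401850
working_age,central,2041-2045,3145977
working_age,central,2046-2050,2884415
working_age,central,2051-2055,2696655
working_age,central,2056-2060,2510505
working_age,central,2061-2065,2325069
working_age,central,2066-2070,2187707
older,central,2020,942284
older,central,2021-2025,1075576
older,central,2026-2030,1301137
older,central,2031-2035,1490842
older,central,2036-2040,1626707
older,central,2041-2045,1745415
older,central,2046-2050,1840408
older,central,2051-2055,1838748
older,central,2056-2060,1816105
older,central,2061-2065,1780903
older,central,2066-2070,1689957
children,southern,2020,820861
children,southern,2021-2025,787714
children,southern,2026-2030,742757
children,southern,2031-2035,700080
children,southern,2036-2040,705112
children,southern,2041-2045,693138
children,southern,2046-2050,663051
children,southern,2051-2055,623489
children,southern,2056-2060,587565
children,southern,2061-2065,560312
children,southern,2066-2070,542855
working_age,southern,2020,4656515
working_age,southern,2021-2025,4525912
working_age,southern,2026-2030,4283239
working_age,southern,2031-2035,4050412
working_age,southern,2036-2040,3787429
working_age,southern,2041-2045,3502555
working_age,southern,2046-2050,3211346
working_age,southern,2051-2055,3002304
working_age,southern,2056-2060,2795056
working_age,southern,2061-2065,2588601
working_age,southern,2066-2070,2435670
older,southern,2020,1049086
older,southern,2021-2025,1197486
older,southern,2026-2030,1448613
older,southern,2031-2035,1659820
older,southern,2036-2040,1811085
older,southern,2041-2045,1943247
older,southern,2046-2050,2049007
older,southern,2051-2055,2047159
older,southern,2056-2060,2021949
older,southern,2061-2065,1982758
older,southern,2066-2070,1881504
children,eastern,2020,72900
children,eastern,2021-2025,69956
children,eastern,2026-2030,65963
children,eastern,2031-2035,62173
children,eastern,2036-2040,62620
children,eastern,2041-2045,61557
children,eastern,2046-2050,58885
children,eastern,2051-2055,55371
children,eastern,2056-2060,52181
children,eastern,2061-2065,49761
children,eastern,2066-2070,48210
working_age,eastern,2020,413539
working_age,eastern,2021-2025,401940
working_age,eastern,2026-2030,380389
working_age,eastern,2031-2035,359712
working_age,eastern,2036-2040,336357
working_age,eastern,2041-2045,311057
working_age,eastern,2046-2050,285195
working_age,eastern,2051-2055,266631
working_age,eastern,2056-2060,248225
working_age,eastern,2061-2065,229890
working_age,eastern,2066-2070,216309
older,eastern,2020,93168
older,eastern,2021-2025,106347
older,eastern,2026-2030,128649
older,eastern,2031-2035,147406
older,eastern,2036-2040,160840
older,eastern,2041-2045,172577
older,eastern,2046-2050,181970
older,eastern,2051-2055,181805
older,eastern,2056-2060,179567
older,eastern,2061-2065,176086
older,eastern,2066-2070,167094
children,taiwan,2020,2963396
children,taiwan,2021-2025,2843731
children,taiwan,2026-2030,2681433
children,taiwan,2031-2035,2527363
children,taiwan,2036-2040,2545531
children,taiwan,2041-2045,2502302
children,taiwan,2046-2050,2393687
children,taiwan,2051-2055,2250863
children,taiwan,2056-2060,2121174
children,taiwan,2061-2065,2022787
children,taiwan,2066-2070,1959767
working_age,taiwan,2020,16810525
working_age,taiwan,2021-2025,16339032
working_age,taiwan,2026-2030,15462958
working_age,taiwan,2031-2035,14622428
working_age,taiwan,2036-2040,13673029
working_age,taiwan,2041-2045,12644604
working_age,taiwan,2046-2050,11593307
working_age,taiwan,2051-2055,10838644
working_age,taiwan,2056-2060,10090456
working_age,taiwan,2061-2065,9345131
working_age,taiwan,2066-2070,8793034
older,taiwan,2020,3787315
older,taiwan,2021-2025,4323054
older,taiwan,2026-2030,5229648
older,taiwan,2031-2035,5992129
older,taiwan,2036-2040,6538212
older,taiwan,2041-2045,7015332
older,taiwan,2046-2050,7397137
older,taiwan,2051-2055,7390467
older,taiwan,2056-2060,7299455
older,taiwan,2061-2065,7157971
older,taiwan,2066-2070,6792433
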