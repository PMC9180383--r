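age_group,region,period,value
children,northern,2020,0
children,northern,2021-2025,715
children,northern,2026-2030,1471
children,northern,2031-2035,2296
children,northern,2036-2040,3436
children,northern,2041-2045,4792
children,northern,2046-2050,6365
children,northern,2051-2055,8935
children,northern,2056-2060,12955
children,northern,2061-2065,21035
children,northern,2066-2070,45358
working_age,northern,2020,0
working_age,northern,2021-2025,48315
working_age,northern,2026-2030,99877
working_age,northern,2031-2035,156154
working_age,northern,2036-2040,217323
working_age,northern,2041-2045,284758
working_age,northern,2046-2050,362748
working_age,northern,2051-2055,504530
working_age,northern,2056-2060,724782
working_age,northern,2061-2065,1140927
working_age,northern,2066-2070,2395247
older,northern,2020,0
older,northern,2021-2025,13476
older,northern,2026-2030,35643
older,northern,2031-2035,67488
older,northern,2036-2040,109704
older,northern,2041-2045,166786
older,northern,2046-2050,244345
older,northern,2051-2055,363041
older,northern,2056-2060,553301
older,northern,2061-2065,922379
older,northern,2066-2070,1954538
children,central,2020,0
children,central,2021-2025,367
children,central,2026-2030,755
children,central,2031-2035,1179
children,central,2036-2040,1765
children,central,2041-2045,2462
children,central,2046-2050,3269
children,central,2051-2055,4578
children,central,2056-2060,6643
children,central,2061-2065,10789
children,central,2066-2070,23323
working_age,central,2020,0
working_age,central,2021-2025,23483
working_age,central,2026-2030,48513
working_age,central,2031-2035,75879
working_age,central,2036-2040,105593
working_age,central,2041-2045,138383
working_age,central,2046-2050,176175
working_age,central,2051-2055,245130
working_age,central,2056-2060,352122
working_age,central,2061-2065,554539
working_age,central,2066-2070,1164150
older,central,2020,0
older,central,2021-2025,6632
older,central,2026-2030,17525
older,central,2031-2035,33204
older,central,2036-2040,53902
older,central,2041-2045,82021
older,central,2046-2050,120089
older,central,2051-2055,178545
older,central,2056-2060,271990
older,central,2061-2065,453535
older,central,2066-2070,960276
children,southern,2020,0
children,southern,2021-2025,1019
children,southern,2026-2030,2096
children,southern,2031-2035,3269
children,southern,2036-2040,4898
children,southern,2041-2045,6824
children,southern,2046-2050,9067
children,southern,2051-2055,12689
children,southern,2056-2060,18454
children,southern,2061-2065,29924
children,southern,2066-2070,64666
working_age,southern,2020,0
working_age,southern,2021-2025,55673
working_age,southern,2026-2030,115023
working_age,southern,2031-2035,179887
working_age,southern,2036-2040,250325
working_age,southern,2041-2045,328092
working_age,southern,2046-2050,417754
working_age,southern,2051-2055,581275
working_age,southern,2056-2060,834938
working_age,southern,2061-2065,1314576
working_age,southern,2066-2070,2759959
older,southern,2020,0
older,southern,2021-2025,55024
older,southern,2026-2030,145317
older,southern,2031-2035,275351
older,southern,2036-2040,447158
older,southern,2041-2045,679971
older,southern,2046-2050,995696
older,southern,2051-2055,1480558
older,southern,2056-2060,2256149
older,southern,2061-2065,3761330
older,southern,2066-2070,7963442
children,eastern,2020,0
children,eastern,2021-2025,29
children,eastern,2026-2030,63
children,eastern,2031-2035,104
children,eastern,2036-2040,155
children,eastern,2041-2045,220
children,eastern,2046-2050,305
children,eastern,2051-2055,454
children,eastern,2056-2060,700
children,eastern,2061-2065,1191
children,eastern,2066-2070,2658
working_age,eastern,2020,0
working_age,eastern,2021-2025,2757
working_age,eastern,2026-2030,5661
working_age,eastern,2031-2035,8773
working_age,eastern,2036-2040,12192
working_age,eastern,2041-2045,16040
working_age,eastern,2046-2050,20558
working_age,eastern,2051-2055,28045
working_age,eastern,2056-2060,39328
working_age,eastern,2061-2065,66905
working_age,eastern,2066-2070,134344
older,eastern,2020,0
older,eastern,2021-2025,678
older,eastern,2026-2030,1478
older,eastern,2031-2035,3665
older,eastern,2036-2040,5456
older,eastern,2041-2045,7731
older,eastern,2046-2050,10735
older,eastern,2051-2055,15975
older,eastern,2056-2060,24643
older,eastern,2061-2065,41922
older,eastern,2066-2070,93531
children,taiwan,2020,0
children,taiwan,2021-2025,704
children,taiwan,2026-2030,1451
children,taiwan,2031-2035,2261
children,taiwan,2036-2040,3389
children,taiwan,2041-2045,4720
children,taiwan,2046-2050,6270
children,taiwan,2051-2055,8780
children,taiwan,2056-2060,12759
children,taiwan,2061-2065,20692
children,taiwan,2066-2070,44723
working_age,taiwan,2020,0
working_age,taiwan,2021-2025,42761
working_age,taiwan,2026-2030,88351
working_age,taiwan,2031-2035,138170
working_age,taiwan,2036-2040,192278
working_age,taiwan,2041-2045,252014
working_age,taiwan,2046-2050,320885
working_age,taiwan,2051-2055,446480
working_age,taiwan,2056-2060,641320
working_age,taiwan,2061-2065,1009752
working_age,taiwan,2066-2070,2119758
older,taiwan,2020,0
older,taiwan,2021-2025,34817
older,taiwan,2026-2030,91947
older,taiwan,2031-2035,174239
older,taiwan,2036-2040,282928
older,taiwan,2041-2045,430241
older,taiwan,2046-2050,630022
older,taiwan,2051-2055,936866
older,taiwan,2056-2060,1427554
older,taiwan,2061-2065,2379924
older,taiwan,2066-2070,5038875
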