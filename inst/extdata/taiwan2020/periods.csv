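id,start_year,end_year
2020,2020,2020
2021-2025,2021,2025
2026-2030,2026,2030
2031-2035,2031,2035
2036-2040,2036,2040
2041-2045,2041,2045
2046-2050,2046,2050
2051-2055,2051,2055
2056-2060,2056,2060
2061-2065,2061,2065
2066-2070,2066,2070
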