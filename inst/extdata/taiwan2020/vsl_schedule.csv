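age_group,period,vsl_usd
children,2020,2194866
children,2021-2025,2167689
children,2026-2030,2151162
children,2031-2035,2134532
children,2036-2040,2117808
children,2041-2045,2100999
children,2046-2050,2084114
children,2051-2055,2067906
children,2056-2060,2050987
children,2061-2065,2034013
children,2066-2070,2016989
working_age,2020,12326614
working_age,2021-2025,12173987
working_age,2026-2030,12081168
working_age,2031-2035,11987772
working_age,2036-2040,11893849
working_age,2041-2045,11799449
working_age,2046-2050,11704618
working_age,2051-2055,11613595
working_age,2056-2060,11518578
working_age,2061-2065,11423246
working_age,2066-2070,11327640
older,2020,25745461
older,2021-2025,25426682
older,2026-2030,25232819
older,2031-2035,25037751
older,2036-2040,24841583
older,2041-2045,24644418
older,2046-2050,24446355
older,2051-2055,24256242
older,2056-2060,24057790
older,2061-2065,23858678
older,2066-2070,23658995
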