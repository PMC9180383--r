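age_group,region,period,value,flag
children,northern,2020,47848,
children,northern,2021-2025,45305,
children,northern,2026-2030,42378,reconstructed
children,northern,2031-2035,39702,
children,northern,2036-2040,39603,
children,northern,2041-2045,38658,
children,northern,2046-2050,36680,
children,northern,2051-2055,34327,
children,northern,2056-2060,31995,
children,northern,2061-2065,30307,
children,northern,2066-2070,29045,
working_age,northern,2020,3191360,
working_age,northern,2021-2025,3062975,
working_age,northern,2026-2030,2877734,
working_age,northern,2031-2035,2699646,
working_age,northern,2036-2040,2504845,
working_age,northern,2041-2045,2297353,
working_age,northern,2046-2050,2090445,
working_age,northern,2051-2055,1938309,
working_age,northern,2056-2060,1789987,
working_age,northern,2061-2065,1643805,
working_age,northern,2066-2070,1533762,
older,northern,2020,759491,
older,northern,2021-2025,854337,
older,northern,2026-2030,1026976,
older,northern,2031-2035,1166759,
older,northern,2036-2040,1264437,
older,northern,2041-2045,1345585,
older,northern,2046-2050,1408110,
older,northern,2051-2055,1394734,
older,northern,2056-2060,1366482,
older,northern,2061-2065,1328928,
older,northern,2066-2070,1251561,
children,central,2020,82527,
children,central,2021-2025,78254,
children,central,2026-2030,73139,
children,central,2031-2035,68518,
children,central,2036-2040,68405,
children,central,2041-2045,66812,
children,central,2046-2050,63357,
children,central,2051-2055,59142,
children,central,2056-2060,55172,
children,central,2061-2065,52274,
children,central,2066-2070,50223,
working_age,central,2020,5214158,
working_age,central,2021-2025,5005944,
working_age,central,2026-2030,4700782,
working_age,central,2031-2035,4411500,
working_age,central,2036-2040,4092673,
working_age,central,2041-2045,3754585,
working_age,central,2046-2050,3414237,
working_age,central,2051-2055,3167027,
working_age,central,2056-2060,2924567,
working_age,central,2061-2065,2686747,
working_age,central,2066-2070,2506807,
older,central,2020,1253804,
older,central,2021-2025,1413724,
older,central,2026-2030,1698169,
older,central,2031-2035,1930411,
older,central,2036-2040,2089177,
older,central,2041-2045,2225391,
older,central,2046-2050,2327293,
older,central,2051-2055,2306769,
older,central,2056-2060,2259026,
older,central,2061-2065,2197384,
older,central,2066-2070,2067796,
children,southern,2020,377956,
children,southern,2021-2025,358319,
children,southern,2026-2030,335151,
children,southern,2031-2035,313563,
children,southern,2036-2040,313224,
children,southern,2041-2045,305485,
children,southern,2046-2050,289900,
children,southern,2051-2055,270482,
children,southern,2056-2060,252887,
children,southern,2061-2065,239200,
children,southern,2066-2070,229735,
working_age,southern,2020,20398082,
working_age,southern,2021-2025,19580641,
working_age,southern,2026-2030,18388746,
working_age,southern,2031-2035,17255199,
working_age,southern,2036-2040,16007931,
working_age,southern,2041-2045,14686774,
working_age,southern,2046-2050,13357311,
working_age,southern,2051-2055,12390544,
working_age,southern,2056-2060,11441404,
working_age,southern,2061-2065,10508244,
working_age,southern,2066-2070,9805205,
older,southern,2020,17167073,
older,southern,2021-2025,19352248,
older,southern,2026-2030,23231857,
older,southern,2031-2035,26412324,
older,southern,2036-2040,28595147,
older,southern,2041-2045,30438321,
older,southern,2046-2050,31836488,
older,southern,2051-2055,31559797,
older,southern,2056-2060,30916666,
older,southern,2061-2065,30066706,
older,southern,2066-2070,28291426,
children,eastern,2020,219,
children,eastern,2021-2025,217,
children,eastern,2026-2030,215,
children,eastern,2031-2035,213,
children,eastern,2036-2040,212,
children,eastern,2041-2045,210,
children,eastern,2046-2050,208,
children,eastern,2051-2055,207,
children,eastern,2056-2060,205,
children,eastern,2061-2065,203,
children,eastern,2066-2070,202,
working_age,eastern,2020,20955,
working_age,eastern,2021-2025,20696,
working_age,eastern,2026-2030,19330,
working_age,eastern,2031-2035,17982,
working_age,eastern,2036-2040,16651,
working_age,eastern,2041-2045,15339,
working_age,eastern,2046-2050,14046,
working_age,eastern,2051-2055,12775,
working_age,eastern,2056-2060,11519,
working_age,eastern,2061-2065,11423,
working_age,eastern,2066-2070,10195,
older,eastern,2020,5149,
older,eastern,2021-2025,5085,
older,eastern,2026-2030,5047,
older,eastern,2031-2035,7511,
older,eastern,2036-2040,7452,
older,eastern,2041-2045,7393,
older,eastern,2046-2050,7334,
older,eastern,2051-2055,7277,
older,eastern,2056-2060,7217,
older,eastern,2061-2065,7158,
older,eastern,2066-2070,7098,
children,taiwan,2020,472555,
children,taiwan,2021-2025,447845,
children,taiwan,2026-2030,419261,
children,taiwan,2031-2035,392113,
children,taiwan,2036-2040,391794,
children,taiwan,2041-2045,381962,
children,taiwan,2046-2050,362427,
children,taiwan,2051-2055,338309,
children,taiwan,2056-2060,316057,
children,taiwan,2061-2065,299000,
children,taiwan,2066-2070,287219,
working_age,taiwan,2020,28322862,
working_age,taiwan,2021-2025,27186948,
working_age,taiwan,2026-2030,25533549,
working_age,taiwan,2031-2035,23958761,
working_age,taiwan,2036-2040,22227225,
working_age,taiwan,2041-2045,20392987,
working_age,taiwan,2046-2050,18547138,
working_age,taiwan,2051-2055,17204379,
working_age,taiwan,2056-2060,15886423,
working_age,taiwan,2061-2065,14590912,
working_age,taiwan,2066-2070,13613558,
older,taiwan,2020,19636063,
older,taiwan,2021-2025,22136469,
older,taiwan,2026-2030,26572682,
older,taiwan,2031-2035,30213054,
older,taiwan,2036-2040,32706429,
older,taiwan,2041-2045,34815170,
older,taiwan,2046-2050,36415290,
older,taiwan,2051-2055,36100566,
older,taiwan,2056-2060,35362545,
older,taiwan,2061-2065,34389899,
older,taiwan,2066-2070,32360774,
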