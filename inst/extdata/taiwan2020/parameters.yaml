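# Valuation and risk parameters for the Taiwan 2020-2070 scenario.
# Monetary values in USD unless noted; the TWD->USD conversion uses the
# 2001-2020 average exchange rate.
coefficients:
  csf: 1.0e-4               # cancer slope factor, per (pg-TEQ/kg/day)
  cancer_survival_rate: 0.7722  # 1-year all-cancer survival, 2013-2017
value_transfer:
  vsl_base: 11790000        # hedonic-wage VSL estimate, 2014 USD
  earnings_elasticity: 0.2476
  wage_base: 1317.18        # average monthly earnings, USD, 2014
  wage_target: 1385.64      # average monthly earnings, USD, 2020
  cpi_base: 98.93           # CPI 2014 (2015 = 100)
  cpi_target: 102.55        # CPI 2020 (2015 = 100)
  exchange_rate: 31.807     # TWD per USD, 2001-2020 average
discount:
  annual_rate: 0.02         # 20-year real government-bond rate
  base_year: 2020
  convention: fixture       # published schedule is canonical; see vignette
provenance: >
  Compiled from published Taiwan EPA WRF/Chem dispersion-simulation
  outputs (2010 emission inventory, 57.8 g I-TEQ/year nationally),
  National Development Council medium-variant population projections
  to 2070, Taiwan Cancer Registry survival rates, and a hedonic-wage
  VSL study transferred from 2014 to 2020.
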