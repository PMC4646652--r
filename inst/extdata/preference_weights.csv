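landowner,policy,BIRDS,CARBON,WATER_QUALITY,FINANCIAL_PROFIT,BIODIVERSITY
PROFIT_MAXIMIZING_PRODUCER,OUTREACH_MARKETING,0.15,0.21,0.21,0.30,0.12
PROFIT_MAXIMIZING_PRODUCER,REGULATORY_ENFORCEMENT,0.00,0.08,0.08,0.83,0.00
PROFIT_MAXIMIZING_PRODUCER,PUBLIC_LAND_ACQUISITION,0.00,0.00,0.00,1.00,0.00
PROFIT_MAXIMIZING_PRODUCER,BEST_MANAGEMENT_PRACTICES,0.00,0.00,0.00,1.00,0.00
PROFIT_MAXIMIZING_PRODUCER,ECOSYSTEM_SERVICES_PAYMENTS,0.03,0.15,0.15,0.51,0.15
PROFIT_MAXIMIZING_PRODUCER,ECONOMIC_INCENTIVES,0.03,0.13,0.13,0.67,0.03
PROFIT_MAXIMIZING_PRODUCER,STATUS_QUO,0.00,0.00,0.00,1.00,0.00
SMALL_SCALE_FARMER,OUTREACH_MARKETING,0.23,0.07,0.10,0.33,0.27
SMALL_SCALE_FARMER,REGULATORY_ENFORCEMENT,0.20,0.00,0.10,0.50,0.20
SMALL_SCALE_FARMER,PUBLIC_LAND_ACQUISITION,0.20,0.00,0.20,0.40,0.20
SMALL_SCALE_FARMER,BEST_MANAGEMENT_PRACTICES,0.23,0.06,0.16,0.32,0.23
SMALL_SCALE_FARMER,ECOSYSTEM_SERVICES_PAYMENTS,0.24,0.00,0.17,0.34,0.24
SMALL_SCALE_FARMER,ECONOMIC_INCENTIVES,0.26,0.00,0.15,0.37,0.22
SMALL_SCALE_FARMER,STATUS_QUO,0.23,0.00,0.09,0.45,0.23
CONSERVATIONIST,OUTREACH_MARKETING,0.24,0.17,0.17,0.19,0.24
CONSERVATIONIST,REGULATORY_ENFORCEMENT,0.29,0.11,0.11,0.23,0.26
CONSERVATIONIST,PUBLIC_LAND_ACQUISITION,0.29,0.12,0.12,0.24,0.24
CONSERVATIONIST,BEST_MANAGEMENT_PRACTICES,0.25,0.15,0.18,0.20,0.23
CONSERVATIONIST,ECOSYSTEM_SERVICES_PAYMENTS,0.26,0.10,0.18,0.23,0.23
CONSERVATIONIST,ECONOMIC_INCENTIVES,0.27,0.11,0.16,0.24,0.22
CONSERVATIONIST,STATUS_QUO,0.30,0.12,0.12,0.24,0.21
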