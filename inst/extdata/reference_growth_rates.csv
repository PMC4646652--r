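policy,PROFIT_MAXIMIZING_PRODUCER,SMALL_SCALE_FARMER,CONSERVATIONIST
OUTREACH_MARKETING,0.0287,0.0353,0.0427
REGULATORY_ENFORCEMENT,-0.0569,0.0235,0.0431
PUBLIC_LAND_ACQUISITION,-0.0863,0.0308,0.0442
BEST_MANAGEMENT_PRACTICES,-0.0715,0.0361,0.0436
ECOSYSTEM_SERVICES_PAYMENTS,0.0041,0.0376,0.0427
ECONOMIC_INCENTIVES,-0.0106,0.0370,0.0435
STATUS_QUO,-0.0733,0.0292,0.0438
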