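key,value
mean_daily_donations,2160
mean_daily_demand,2000
dispersion,400
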