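labels,share,ci_low,ci_high
ICU,18.61,18.59,18.64
CS,7.68,7.63,7.73
CCU,4.72,4.71,4.73
TR,2.09,1.97,2.21
CS;ICU,16.43,15.69,17.13
CS;CCU,3.59,3.58,3.60
ICU;CCU,1.76,1.73,1.78
TR;ICU,1.23,1.15,1.31
CS;TR,0.33,0.28,0.37
TR;CCU,0.23,0.21,0.24
CS;ICU;CCU,3.85,3.69,4.01
CS;TR;ICU,1.03,0.84,1.22
CS;TR;CCU,0.13,0.11,0.15
TR;ICU;CCU,0.11,0.10,0.12
CS;TR;ICU;CCU,0.18,0.14,0.22
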