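phenotype,probability
O-,0.066
O+,0.374
A-,0.063
A+,0.357
B-,0.015
B+,0.085
AB-,0.006
AB+,0.034
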