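family,parameter,value
logistic,A,3136.722
logistic,b,37.106
logistic,k,0.736
gompertz,A,6854.354
gompertz,b,4.882
gompertz,k,0.241
weibull,A,13500.860
weibull,b,13436.664
weibull,k,0.005
weibull,lambda,1.941
hossfeld,A,8872.315
hossfeld,b1,106.170
hossfeld,b2,1.963
von_bertalanffy,A,20692.727
von_bertalanffy,b,0.885
von_bertalanffy,k,0.086
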