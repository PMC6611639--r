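"strain","f","theta","m","rho_L","gamma_L","rho_c","gamma_c","mu"
"A",5.955,1.393,2,1e-09,0.01,2.6e-11,0.005,2
"B",4.083,1.633,2,1e-09,0.01,2.6e-11,0.005,2
"C",24.839,1.364,2,1e-09,0.01,2.6e-11,0.005,2
"D",8.345,1.394,2,1e-09,0.01,2.6e-11,0.005,2
"E",6.951,1.815,2,1e-09,0.01,2.6e-11,0.005,2
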