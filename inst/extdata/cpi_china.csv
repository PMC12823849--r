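year,rate
2019,0.029
2020,0.025
2021,0.009
2022,0.020
2023,0.002
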