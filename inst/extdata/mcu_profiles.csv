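name,f_clk_mhz,t_i_ms
STM32H5,250,15.63
B-U5U5I,160,23.90
STM32G4,170,27.35
STM32F4,84,52.80
STM32F7,216,13.85
STM32H7,480,6.28
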