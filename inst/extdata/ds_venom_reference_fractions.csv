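venom,fraction_id,share_pct,identified
thailand,F4,9.83,1
thailand,F5,9.14,1
thailand,F6,3.14,1
thailand,F7,0.92,1
thailand,F8,3.19,1
thailand,F9,26.23,1
thailand,F10,23.34,1
thailand,F11,4.17,1
thailand,F12,0.54,1
thailand,F13,1.17,1
thailand,F14,1.48,1
thailand,F15,5.17,1
thailand,F16,11.68,1
indonesia,F4,6.21,1
indonesia,F5,0.85,1
indonesia,F6,7.47,0
indonesia,F7,32.61,1
indonesia,F8,31.47,1
indonesia,F9,9.06,1
indonesia,F10,2.78,1
indonesia,F11,8.97,0
indonesia,F12,4.90,1
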