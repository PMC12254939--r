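{"name":"large-quenching","phases":[{"label":"dark","duration_s":360,"actinic_ppfd":0},{"label":"highlight","duration_s":540,"actinic_ppfd":800},{"label":"relax","duration_s":1620,"actinic_ppfd":0},{"label":"ramp100","duration_s":180,"actinic_ppfd":100},{"label":"ramp200","duration_s":180,"actinic_ppfd":200},{"label":"ramp300","duration_s":180,"actinic_ppfd":300},{"label":"ramp600","duration_s":180,"actinic_ppfd":600},{"label":"ramp800","duration_s":180,"actinic_ppfd":800},{"label":"ramp1000","duration_s":180,"actinic_ppfd":1000},{"label":"ramp1200","duration_s":180,"actinic_ppfd":1200}],"pulse_times_s":[180,360,540,720,900,1080,1260,1440,1620,1800,1980,2160,2340,2520,2700,2880,3060,3240,3420,3600],"pulse_labels":["Fm","HL1","HL2","HL3","D1","D2","D3","D4","D5","D6","D7","D8","D9","R1","R2","R3","R4","R5","R6","R7"],"pulse_duration_s":0.8,"pulse_ppfd":3000,"fo_window_s":[0,150]}
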