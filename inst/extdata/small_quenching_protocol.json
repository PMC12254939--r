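{"name":"small-quenching","phases":[{"label":"dark","duration_s":21.7,"actinic_ppfd":0},{"label":"actinic","duration_s":70,"actinic_ppfd":155},{"label":"relax","duration_s":100,"actinic_ppfd":0}],"pulse_times_s":[5.06,31.7,41.7,51.7,71.7,91.7,121.7,181.7,191.7],"pulse_labels":["Fm","L1","L2","L3","L4","Lss","D1","D2","D3"],"pulse_duration_s":0.8,"pulse_ppfd":1085,"fo_window_s":[0,4.5]}
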