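[{"name":"Constant-155","start_clock":"06:00","intervals":[{"start_h":0,"duration_h":18,"ppfd":155},{"start_h":18,"duration_h":6,"ppfd":0}]},{"name":"High-Low","start_clock":"06:00","intervals":[{"start_h":0,"duration_h":6,"ppfd":275},{"start_h":6,"duration_h":12,"ppfd":95},{"start_h":18,"duration_h":6,"ppfd":0}]},{"name":"Sunlike","start_clock":"06:00","intervals":[{"start_h":0,"duration_h":6,"ppfd":95},{"start_h":6,"duration_h":6,"ppfd":275},{"start_h":12,"duration_h":6,"ppfd":95},{"start_h":18,"duration_h":6,"ppfd":0}]},{"name":"Low-High","start_clock":"06:00","intervals":[{"start_h":0,"duration_h":12,"ppfd":95},{"start_h":12,"duration_h":6,"ppfd":275},{"start_h":18,"duration_h":6,"ppfd":0}]},{"name":"Constant-196","start_clock":"11:00","intervals":[{"start_h":0,"duration_h":18,"ppfd":196},{"start_h":18,"duration_h":6,"ppfd":0}]},{"name":"Split-Night","start_clock":"11:00","intervals":[{"start_h":0,"duration_h":6,"ppfd":196},{"start_h":6,"duration_h":3,"ppfd":0},{"start_h":9,"duration_h":12,"ppfd":196},{"start_h":21,"duration_h":3,"ppfd":0}]},{"name":"Price-Based","start_clock":"11:00","intervals":[{"start_h":0,"duration_h":6,"ppfd":100},{"start_h":6,"duration_h":3,"ppfd":0},{"start_h":9,"duration_h":3,"ppfd":150},{"start_h":12,"duration_h":6,"ppfd":340},{"start_h":18,"duration_h":3,"ppfd":150},{"start_h":21,"duration_h":3,"ppfd":0}]},{"name":"Constant 05-23","start_clock":"05:00","intervals":[{"start_h":0,"duration_h":18,"ppfd":196},{"start_h":18,"duration_h":6,"ppfd":0}]},{"name":"Constant 11-05","start_clock":"11:00","intervals":[{"start_h":0,"duration_h":18,"ppfd":196},{"start_h":18,"duration_h":6,"ppfd":0}]},{"name":"Constant 17-11","start_clock":"17:00","intervals":[{"start_h":0,"duration_h":18,"ppfd":196},{"start_h":18,"duration_h":6,"ppfd":0}]},{"name":"Constant 23-17","start_clock":"23:00","intervals":[{"start_h":0,"duration_h":18,"ppfd":196},{"start_h":18,"duration_h":6,"ppfd":0}]}]
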