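{"M":[[0.6168585015771636,0.095155758063436638],[0.73415117914975037,0.98385400442638959],[0.28373867410877884,0.15158060456908884]],"maxC":[1.4899033632885195,0.25157087694723596],"alpha":1,"beta":0.14999999999999999,"I0":255}
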