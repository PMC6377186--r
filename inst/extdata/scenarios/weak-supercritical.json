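{"tau_r":1,"tau_1":1.7,"tau_2":1.7,"I_1":0.4,"I_2":0.4,"beta":1,"theta":0.99,"T":8,"sigma":0.3,"t_on":0,"t_max":0.5,"mode":"clamped_history","target":1}
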