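{"outer_nodes":[[100,200],[107.612046748871,161.731656763491],[129.289321881345,129.289321881345],[161.731656763491,107.612046748871],[200,100],[238.268343236509,107.612046748871],[270.710678118655,129.289321881345],[292.387953251129,161.731656763491],[300,200],[292.387953251129,238.268343236509],[270.710678118655,270.710678118655],[238.268343236509,292.387953251129],[200,300],[161.731656763491,292.387953251129],[129.289321881345,270.710678118655],[107.612046748871,238.268343236509]],"inner_nodes":[[120,200],[126.089637399097,169.385325410793],[143.431457505076,143.431457505076],[169.385325410793,126.089637399097],[200,120],[230.614674589207,126.089637399097],[256.568542494924,143.431457505076],[273.910362600903,169.385325410793],[280,200],[273.910362600903,230.614674589207],[256.568542494924,256.568542494924],[230.614674589207,273.910362600903],[200,280],[169.385325410793,273.910362600903],[143.431457505076,256.568542494924],[126.089637399097,230.614674589207]],"boundary_markers":null,"aboral_anchor":0,"stage_hpf":"blastula"}
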