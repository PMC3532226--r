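{"outer_nodes":[[100.000000000031,200],[107.61204676656,161.731656770818],[129.289325429955,129.289325429955],[161.731870476287,107.612562697202],[200,100.026383509073],[238.065837198031,108.100939573427],[267.524477277079,132.475522722921],[277.338615508977,167.965296561024],[275,200],[277.338615508977,232.034703438976],[267.524477277079,267.524477277079],[238.065837198031,291.899060426573],[200,299.973616490927],[161.731870476287,292.387437302798],[129.289325429955,270.710674570045],[107.61204676656,238.268343229182]],"inner_nodes":[[120.000000000031,200],[126.089637416786,169.38532541812],[143.431461053686,143.431461053686],[169.385539123589,126.090153347428],[200,120.026383509073],[230.412168550729,126.578530223652],[253.382341653348,146.617658346652],[258.861024858751,175.618965208325],[255,200],[258.861024858751,224.381034791675],[253.382341653348,253.382341653348],[230.41216855073,273.421469776348],[200,279.973616490927],[169.385539123589,273.909846652572],[143.431461053686,256.568538946314],[126.089637416786,230.61467458188]],"boundary_markers":[0.416042420430249,0.583957579569752],"aboral_anchor":0,"stage_hpf":"early_gastrula"}
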