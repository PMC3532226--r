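{"outer_nodes":[[100.000000000062,200],[107.612046784249,161.731656778145],[129.289328978565,129.289328978565],[161.732084189083,107.613078645533],[200,100.052767018146],[237.863331159554,108.589832397982],[264.338276435504,135.661723564496],[262.289277766825,174.198936358556],[250,200],[262.289277766825,225.801063641444],[264.338276435504,264.338276435504],[237.863331159554,291.410167602018],[200,299.947232981854],[161.732084189083,292.386921354467],[129.289328978565,270.710671021435],[107.612046784249,238.268343221855]],"inner_nodes":[[120.000000000062,200],[126.089637434474,169.385325425447],[143.431464602296,143.431464602296],[169.385752836385,126.090669295759],[200,120.052767018146],[230.209662512252,127.067423048208],[250.196140811773,149.803859188227],[243.811687116599,181.852605005858],[230,200],[243.811687116599,218.147394994142],[250.196140811773,250.196140811773],[230.209662512252,272.932576951792],[200,279.947232981854],[169.385752836385,273.909330704241],[143.431464602296,256.568535397704],[126.089637434474,230.614674574553]],"boundary_markers":[0.417235225390833,0.582764774609167],"aboral_anchor":0,"stage_hpf":"late_gastrula"}
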