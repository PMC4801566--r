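activity,freq_hz,o1,o2,g1,g2
a01,0.25,0.945817,0.324699,0.957828,0.153553
a02,0.55,0.789141,0.614213,0.849097,0.24235
a03,0.85,0.546948,0.837166,0.719661,0.228943
a04,1.15,0.245485,0.9694,0.624105,0.118987
a05,1.45,-0.082579,0.996584,0.602728,-0.041149
a06,1.75,-0.401695,0.915773,0.664544,-0.183931
a07,2.05,-0.677282,0.735724,0.783484,-0.249146
a08,2.35,-0.879474,0.475947,0.90939,-0.209292
a09,2.65,-0.986361,0.164595,0.989163,-0.081175
a10,2.95,-0.986361,-0.164595,0.989163,0.081175
a11,3.25,-0.879474,-0.475947,0.90939,0.209292
a12,3.55,-0.677282,-0.735724,0.783484,0.249146
a13,3.85,-0.401695,-0.915773,0.664544,0.183931
a14,4.15,-0.082579,-0.996584,0.602728,0.041149
a15,4.45,0.245485,-0.9694,0.624105,-0.118987
a16,4.75,0.546948,-0.837166,0.719661,-0.228943
a17,5.05,0.789141,-0.614213,0.849097,-0.24235
a18,5.35,0.945817,-0.324699,0.957828,-0.153553
a19,5.65,1,0,1,0
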