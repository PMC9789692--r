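treatment,arg_level,feed_intake,arg_intake,egg_production,egg_weight,egg_mass,feed_efficiency,arg_deposition,body_weight,bw_change,arg_mobilization
D1,2.43,13.2,32.0,13.3,5.4,1.0,0.08,6.8,147.2,-34.8,-11.9
D2,3.64,15.5,56.3,36.3,8.8,3.2,0.21,22.4,149.4,-34.3,-11.7
D3,4.85,17.1,82.9,51.2,8.9,4.6,0.27,32.2,151.3,-22.1,-7.5
D4,6.07,19.3,116.9,80.0,9.5,7.6,0.39,53.2,167.1,-24.6,-7.8
D5,9.07,23.4,212.6,92.1,10.8,10.0,0.43,70.2,174.2,-8.9,-3.0
D6,12.13,25.7,311.3,96.4,10.9,10.5,0.41,73.6,179.7,-0.8,-0.3
D7,14.56,22.6,328.7,95.8,10.2,9.8,0.43,68.6,173.3,5.0,1.7
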