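"species","layer_index","z_bottom","z_top","f_medium","b_v","section"
"red",1,0,0.5,0.45,0.05,"roots"
"red",2,0.5,1,0.35,0.05,"roots"
"red",3,1,1.5,0.25,0.05,"roots"
"red",4,1.5,3,0.04,0.15,"trunk"
"red",5,3,4.5,0.1,0.04,"canopy"
"red",6,4.5,6,0.15,0.03,"canopy"
"red",7,6,8,0.12,0.03,"canopy"
"black",1,0,0.3,0.3,0.01,"roots"
"black",2,0.3,0.6,0.08,0.02,"roots"
"black",3,0.6,2.5,0.03,0.2,"trunk"
"black",4,2.5,4,0.08,0.04,"canopy"
"black",5,4,5.5,0.14,0.03,"canopy"
"black",6,5.5,7,0.12,0.03,"canopy"
"black",7,7,9,0.08,0.03,"canopy"
"pioneer",1,0,0.3,0.4,0.01,"roots"
"pioneer",2,0.3,0.8,0.3,0.02,"trunk"
"pioneer",3,0.8,1.3,0.35,0.02,"canopy"
"pioneer",4,1.3,1.8,0.3,0.02,"canopy"
"pioneer",5,1.8,2.2,0.2,0.02,"canopy"
"pioneer",6,2.2,2.6,0.1,0.02,"canopy"
"pioneer",7,2.6,3,0.05,0.02,"canopy"
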