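"item","dimension","a","tau1","tau2","tau3","tau4","tau5","model"
1,"general",1.38,-4.09,-2.27,-0.59,0.82,2.09,"unidimensional"
2,"general",0.98,-5.39,-2.75,-0.71,0.78,2.33,"unidimensional"
3,"general",1.29,-3.77,-1.97,-0.37,0.71,2.05,"unidimensional"
4,"general",0.92,-3.86,-1.77,-0.0900000000000001,1.13,2.55,"unidimensional"
5,"general",1.09,-5.11,-2.8,-1.11,0.21,1.33,"unidimensional"
6,"general",0.95,-3.1,-1.38,0.3,1.97,3.64,"unidimensional"
7,"general",0.49,-7.89,-2.7,0.820000000000001,3.26,5.36,"unidimensional"
1,"voiding",1.6,-3.4,-1.84,-0.4,0.8,1.89,"bidimensional"
2,"storage",1.4,-4.83,-2.59,-0.79,0.51,1.81,"bidimensional"
3,"voiding",1.68,-3.03,-1.55,-0.23,0.65,1.75,"bidimensional"
4,"storage",1.16,-3.65,-1.77,-0.22,0.9,2.17,"bidimensional"
5,"voiding",1.36,-4.16,-2.26,-0.86,0.23,1.16,"bidimensional"
6,"voiding",1.25,-2.46,-1.08,0.27,1.61,2.95,"bidimensional"
7,"storage",0.6,-6.93,-2.53,0.510000000000001,2.6,4.37,"bidimensional"
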