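group,participant,acc_left,acc_right,acc_average,loss_left,loss_right
chimpanzee,Ch1,1.71,2.01,1.85,17.2,14.4
chimpanzee,Ch2,2.15,2.20,2.22,12.5,3.2
chimpanzee,Ch3,2.82,2.12,2.72,20.8,1.8
chimpanzee,Ch4,2.01,2.12,2.07,12.1,21.1
chimpanzee,Ch5,2.42,2.75,2.64,15.2,25.0
chimpanzee,Ch6,2.31,1.89,2.10,27.3,8.2
baboon,B1,1.81,2.07,1.93,14.3,17.6
baboon,B2,2.37,1.88,2.22,16.4,3.0
baboon,B3,1.82,2.18,2.03,4.5,23.9
baboon,B4,1.92,2.12,1.99,3.8,4.8
baboon,B5,2.70,2.70,2.85,0.5,14.3
macaque,CM1,0.99,1.15,1.07,5.1,5.1
macaque,CM2,0.75,0.69,0.72,3.4,6.8
macaque,CM3,1.50,1.41,1.45,10.4,14.0
macaque,CM4,1.10,0.99,1.05,11.2,12.4
macaque,CM5,1.94,1.65,1.80,5.7,13.0
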