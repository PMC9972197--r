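age,qx
60,0.0071741420961866495
61,0.0079020083692842285
62,0.0087033974707197564
63,0.0095856667805742975
64,0.010556895116266025
65,0.011625950295056316
66,0.012802562333405558
67,0.014097402598502845
68,0.015522169206568551
69,0.017089678929231699
70,0.018813965820176044
71,0.020710386705431603
72,0.022795733587498784
73,0.025088352890380465
74,0.02760827131300183
75,0.030377327854709528
76,0.033419311319571418
77,0.036760102285649257
78,0.040427818129381253
79,0.044452959210199851
80,0.048868553731452491
81,0.053710298084027192
82,0.059016688631001665
83,0.064829139886517312
84,0.071192082861237405
85,0.078153035972533591
86,0.085762639334983515
87,0.094074641445856727
88,0.10314582525916179
89,0.11303585841102658
90,0.12380704994710032
91,0.13552399336269197
92,0.14825307318573239
93,0.1620618098432233
94,0.17701801534282602
95,0.19318873063367342
96,0.21063891473278876
97,0.22942985626704077
98,0.24961728055310239
99,0.27124913041172499
100,1
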