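event,arm,mean,sd,distribution
primary_composite,intensive,0.0087761820000000004,0.001431865,beta
stroke,intensive,0.0028402649999999998,0.000817006,beta
acs,intensive,0.0032565039999999999,0.00087464300000000004,beta
acute_hf,intensive,0.00029995500000000002,0.000265844,beta
revascularization,intensive,0.00099949999999999995,0.00048510699999999998,beta
af,intensive,0.0014171030000000001,0.00057750599999999998,beta
cv_death,intensive,0.001062262,0.00050009000000000002,beta
hypotension,intensive,0.0087156879999999992,0.0014269650000000001,beta
dizziness,intensive,0.0026620369999999999,0.00079102800000000004,beta
syncope,intensive,0.00035371099999999999,0.00028867600000000003,beta
fracture,intensive,0.00088498299999999999,0.00045649800000000001,beta
aki,intensive,0.0033864350000000001,0.00090939299999999999,beta
all_cause_death,intensive,0.0039712719999999996,0.00096552699999999999,beta
primary_composite,standard,0.01168397,0.0016448680000000001,beta
stroke,standard,0.004185055,0.00098816099999999999,beta
acs,standard,0.0048381850000000001,0.001062126,beta
acute_hf,standard,0.000899595,0.00045889800000000001,beta
revascularization,standard,0.0019980010000000001,0.00068351999999999996,beta
af,standard,0.0014676139999999999,0.00058596899999999999,beta
cv_death,standard,0.0014676139999999999,0.00058596899999999999,beta
hypotension,standard,0.006685776,0.0012474039999999999,beta
dizziness,standard,0.002882637,0.00082064599999999996,beta
syncope,standard,0.00011717099999999999,0.00016568099999999999,beta
fracture,standard,0.0011147959999999999,0.00051079100000000002,beta
aki,standard,0.0037249140000000002,0.00094941800000000005,beta
all_cause_death,standard,0.0037700950000000002,0.00093808800000000001,beta
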