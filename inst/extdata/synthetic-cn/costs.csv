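component,name,arm,value
intervention,,intensive,1728.2109003023104
intervention,,standard,652.39175282055601
acute_event,stroke,,31469.641856922794
acute_event,acs,,39231.962159004324
acute_event,acute_hf,,24158.686038989857
acute_event,revascularization,,57056.022889920619
acute_event,af,,14137.147545513721
acute_event,cv_death,,18267.769033217202
acute_event,hypotension,,708.10753098006182
acute_event,dizziness,,447.25988103899397
acute_event,syncope,,1855.255251112653
acute_event,fracture,,22172.201467436003
acute_event,aki,,12839.476749703219
chronic_state,chronic_chd,,7175.0449239136278
chronic_state,post_stroke,,11250.289831979924
chronic_state,chronic_hf,,9491.4664492937318
chronic_state,chronic_af,,5498.2193593650782
background,,,4280.0352669572012
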