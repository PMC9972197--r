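component,name,value,duration_weeks
baseline,,0.80000000000000004,NA
age_decrement,,0.0030000000000000001,NA
state_decrement,no_cvd,0,NA
state_decrement,chronic_chd,0.10000000000000001,NA
state_decrement,post_stroke,0.22,NA
state_decrement,chronic_hf,0.14999999999999999,NA
state_decrement,chronic_af,0.059999999999999998,NA
event_decrement,stroke,0.20000000000000001,4
event_decrement,acs,0.14999999999999999,4
event_decrement,acute_hf,0.14999999999999999,4
event_decrement,revascularization,0.12,4
event_decrement,af,0.080000000000000002,2
event_decrement,cv_death,0,2
event_decrement,hypotension,0.10000000000000001,2
event_decrement,dizziness,0.080000000000000002,2
event_decrement,syncope,0.12,2
event_decrement,fracture,0.20000000000000001,12
event_decrement,aki,0.14999999999999999,4
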