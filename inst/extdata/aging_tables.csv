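parameter,age,mean,sd_plus,sd_minus,varied_factor,interp,units
hr,25,73.0,11,11,hr,monoH,beats/min
hr,35,76.3,11,11,hr,monoH,beats/min
hr,45,77.0,11,11,hr,monoH,beats/min
hr,55,77.0,11,11,hr,monoH,beats/min
hr,65,76.3,11,11,hr,monoH,beats/min
hr,75,74.4,11,11,hr,monoH,beats/min
sv,25,66.8,16.0,16.0,sv,linear,ml
sv,35,64.1,15.3,15.3,sv,linear,ml
sv,45,61.3,14.2,14.2,sv,linear,ml
sv,55,58.7,13.6,13.6,sv,linear,ml
sv,65,55.8,12.7,12.7,sv,linear,ml
sv,75,53.6,12.0,12.0,sv,linear,ml
lvet,25,282,24,24,lvet,linear,ms
lvet,35,282,24,24,lvet,linear,ms
lvet,45,282,24,24,lvet,linear,ms
lvet,55,282,24,24,lvet,linear,ms
lvet,65,282,24,24,lvet,linear,ms
lvet,75,282,24,24,lvet,linear,ms
pft,25,79,11,11,,linear,ms
pft,35,79,11,11,,linear,ms
pft,45,79,11,11,,linear,ms
pft,55,79,11,11,,linear,ms
pft,65,79,11,11,,linear,ms
pft,75,79,11,11,,linear,ms
rfv,25,0.73,0.63,0.63,,linear,ml
rfv,35,0.73,0.63,0.63,,linear,ml
rfv,45,0.73,0.63,0.63,,linear,ml
rfv,55,0.73,0.63,0.63,,linear,ml
rfv,65,0.73,0.63,0.63,,linear,ml
rfv,75,0.73,0.63,0.63,,linear,ml
map,25,89.2,7.59,7.59,map,spline,mmHg
map,35,92.8,7.47,7.47,map,spline,mmHg
map,45,96.3,7.47,7.47,map,spline,mmHg
map,55,96.2,7.35,7.35,map,spline,mmHg
map,65,95.4,7.23,7.23,map,spline,mmHg
map,75,94.2,7.10,7.10,map,spline,mmHg
dbp,25,74.7,5.7,5.7,,linear,mmHg
dbp,35,77.3,6.0,6.0,,linear,mmHg
dbp,45,78.9,6.1,6.1,,linear,mmHg
dbp,55,77.4,6.2,6.2,,linear,mmHg
dbp,65,74.8,6.6,6.6,,linear,mmHg
dbp,75,71.7,7.2,7.2,,linear,mmHg
prox_aortic_length,25,80.0,0,0,,linear,mm
prox_aortic_length,35,86.4,0,0,,linear,mm
prox_aortic_length,45,92.8,0,0,,linear,mm
prox_aortic_length,55,99.2,0,0,,linear,mm
prox_aortic_length,65,105.6,0,0,,linear,mm
prox_aortic_length,75,112.0,0,0,,linear,mm
asc_aorta_diam,25,36.7,3.18,3.18,diameter,linear,mm
asc_aorta_diam,35,37.8,3.31,3.31,diameter,linear,mm
asc_aorta_diam,45,39.0,3.43,3.43,diameter,linear,mm
asc_aorta_diam,55,40.2,3.55,3.55,diameter,linear,mm
asc_aorta_diam,65,41.4,3.67,3.67,diameter,linear,mm
asc_aorta_diam,75,42.6,3.67,3.67,diameter,linear,mm
desc_thor_diam,25,24.4,2.08,2.08,diameter,linear,mm
desc_thor_diam,35,25.2,2.20,2.20,diameter,linear,mm
desc_thor_diam,45,26.0,2.33,2.33,diameter,linear,mm
desc_thor_diam,55,26.8,2.33,2.33,diameter,linear,mm
desc_thor_diam,65,27.6,2.45,2.45,diameter,linear,mm
desc_thor_diam,75,28.3,2.45,2.45,diameter,linear,mm
abd_aorta_diam,25,14.5,1.22,1.22,diameter,linear,mm
abd_aorta_diam,35,15.0,1.35,1.35,diameter,linear,mm
abd_aorta_diam,45,15.4,1.35,1.35,diameter,linear,mm
abd_aorta_diam,55,15.9,1.35,1.35,diameter,linear,mm
abd_aorta_diam,65,16.3,1.47,1.47,diameter,linear,mm
abd_aorta_diam,75,16.8,1.47,1.47,diameter,linear,mm
carotid_diam,25,6.10,0.55,0.55,diameter,linear,mm
carotid_diam,35,6.35,0.55,0.55,diameter,linear,mm
carotid_diam,45,6.60,0.55,0.55,diameter,linear,mm
carotid_diam,55,6.85,0.55,0.55,diameter,linear,mm
carotid_diam,65,7.10,0.55,0.55,diameter,linear,mm
carotid_diam,75,7.35,0.55,0.55,diameter,linear,mm
pwv_aortic,25,5.9,0.919,0.551,pwv,linear,m/s
pwv_aortic,35,6.5,1.225,0.735,pwv,linear,m/s
pwv_aortic,45,7.3,1.378,0.827,pwv,linear,m/s
pwv_aortic,55,8.0,1.684,1.010,pwv,linear,m/s
pwv_aortic,65,8.9,1.990,1.194,pwv,linear,m/s
pwv_aortic,75,9.7,2.450,1.470,pwv,linear,m/s
pwv_arm,25,8.9,0.919,0.551,pwv,linear,m/s
pwv_arm,35,9.5,1.225,0.735,pwv,linear,m/s
pwv_arm,45,10.4,1.225,0.735,pwv,linear,m/s
pwv_arm,55,11.1,1.531,0.919,pwv,linear,m/s
pwv_arm,65,12.0,1.990,1.194,pwv,linear,m/s
pwv_arm,75,12.8,2.450,1.470,pwv,linear,m/s
pwv_leg,25,8.7,1.378,0.827,pwv,linear,m/s
pwv_leg,35,9.2,1.684,1.010,pwv,linear,m/s
pwv_leg,45,10.1,1.225,0.735,pwv,linear,m/s
pwv_leg,55,10.7,1.531,0.919,pwv,linear,m/s
pwv_leg,65,11.6,1.837,1.102,pwv,linear,m/s
pwv_leg,75,12.4,2.296,1.378,pwv,linear,m/s
pvc,25,40.1,0,0,,linear,1e-9 m3/Pa (tabulated)
pvc,35,35.5,0,0,,linear,1e-9 m3/Pa (tabulated)
pvc,45,31.0,0,0,,linear,1e-9 m3/Pa (tabulated)
pvc,55,26.4,0,0,,linear,1e-9 m3/Pa (tabulated)
pvc,65,21.9,0,0,,linear,1e-9 m3/Pa (tabulated)
pvc,75,17.3,0,0,,linear,1e-9 m3/Pa (tabulated)
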