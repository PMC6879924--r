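age,quantity,mean,sd
25,aortic_sbp,100.1,8.0
25,aortic_dbp,74.7,5.7
25,aortic_map,89.2,6.2
25,aortic_pp,25.4,7.0
25,brachial_sbp,112.3,8.7
25,brachial_dbp,72.0,5.6
25,brachial_map,88.9,6.1
25,brachial_pp,40.3,8.2
25,pp_amp,1.62,0.15
35,aortic_sbp,104.6,8.4
35,aortic_dbp,77.3,6.0
35,aortic_map,92.8,6.1
35,aortic_pp,27.3,8.3
35,brachial_sbp,115.9,9.1
35,brachial_dbp,74.5,6.1
35,brachial_map,92.5,6.3
35,brachial_pp,41.5,9.2
35,pp_amp,1.56,0.16
45,aortic_sbp,110.1,8.4
45,aortic_dbp,78.9,6.1
45,aortic_map,96.3,6.1
45,aortic_pp,31.3,8.5
45,brachial_sbp,120.4,8.6
45,brachial_dbp,76.3,6.2
45,brachial_map,96.1,6.1
45,brachial_pp,44.1,9.1
45,pp_amp,1.44,0.13
55,aortic_sbp,111.9,8.7
55,aortic_dbp,77.4,6.2
55,aortic_map,96.2,6.0
55,aortic_pp,34.5,9.4
55,brachial_sbp,120.6,8.5
55,brachial_dbp,75.0,6.3
55,brachial_map,96.1,6.0
55,brachial_pp,45.6,9.6
55,pp_amp,1.35,0.13
65,aortic_sbp,113.6,8.7
65,aortic_dbp,74.8,6.6
65,aortic_map,95.4,5.9
65,aortic_pp,38.9,10.2
65,brachial_sbp,120.2,8.3
65,brachial_dbp,72.3,6.6
65,brachial_map,95.2,5.9
65,brachial_pp,47.9,9.8
65,pp_amp,1.26,0.11
75,aortic_sbp,115.1,9.4
75,aortic_dbp,71.7,7.2
75,aortic_map,94.2,5.8
75,aortic_pp,43.4,12.3
75,brachial_sbp,120.1,8.7
75,brachial_dbp,69.5,7.1
75,brachial_map,94.0,5.8
75,brachial_pp,50.6,11.5
75,pp_amp,1.19,0.10
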