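area_id,households,owner_cost,owner_cost_moe,renter_cost,renter_cost_moe,child_above_pov,child_above_pov_moe,pov_above,pov_above_moe,employed,employed_moe
222600,1200,28.9,15.7,32,9.1,89.7,19.5,78.7,10.2,94.9,3.6
222700,1500,28.4,10.2,38.8,15.4,53,26.8,74.7,7.5,78.5,8.5
222800,900,63.3,114.5,39.2,15.6,33.7,29.9,61.9,21,88.9,6.2
222900,1100,46.5,19.7,48.3,23.1,59.2,18.2,64.6,14.8,87.7,31.0
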