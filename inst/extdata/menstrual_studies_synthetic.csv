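study_id,n,measure,lower,upper,p,q,hb_conc
synthetic_study_01,28,iron_loss,1.0508976032,135.687621195,0.025,0.975,135
synthetic_study_02,45,blood_loss,2.43144009469,89.551819354,0.025,0.975,135
synthetic_study_03,60,iron_loss,1.0768494662,80.3153196531,0.025,0.975,135
synthetic_study_04,34,blood_loss,2.37096498536,372.413247921,0.025,0.975,135
synthetic_study_05,90,iron_loss,1.08940541193,35.6720670247,0.025,0.975,135
synthetic_study_06,152,blood_loss,2.46375496477,124.165401978,0.025,0.975,135
synthetic_study_07,40,iron_loss,0.988905936946,118.055642642,0.025,0.975,135
synthetic_study_08,75,blood_loss,2.43338777782,96.9326807442,0.025,0.975,135
synthetic_study_09,110,iron_loss,1.12034789415,80.3474811445,0.025,0.975,135
synthetic_study_10,55,blood_loss,2.33472248426,159.630643765,0.025,0.975,135
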