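state,risk_inadequate_icmr2010,risk_inadequate_new_ear,risk_inadequate_fortified_10,risk_inadequate_fort_supp_24,risk_excess_fortified_10,risk_excess_fort_supp_24
A&N Island,81,51,14,2,0,12
Andhra Pradesh,97,78,26,3,0,0
Arunachal Pradesh,95,80,33,5,0,3
Assam,98,83,33,5,0,0
Bihar,82,49,13,2,0,7
Chandigarh,78,48,20,3,0,14
Chhattisgarh,97,78,31,4,0,1
D&N Haveli,92,73,28,4,0,5
Daman & Diu,83,50,13,2,0,5
Delhi,81,49,13,2,0,8
Goa,95,72,28,4,0,1
Gujarat,76,45,13,2,0,16
Haryana,65,33,8,1,0,27
Himachal Pradesh,66,33,8,1,0,24
Jammu & Kashmir,87,57,16,2,0,4
Jharkhand,90,65,20,3,0,4
Karnataka,89,60,17,2,0,3
Kerala,94,70,22,3,0,1
Lakshadweep,86,56,16,2,0,6
Madhya Pradesh,66,36,9,1,1,29
Maharashtra,79,48,11,1,0,12
Manipur,100,93,37,5,0,0
Meghalaya,100,91,39,5,0,0
Mizoram,98,83,34,5,0,0
Nagaland,99,87,32,4,0,0
Orissa,97,78,25,3,0,0
Puducherry,94,68,20,3,0,0
Punjab,66,34,8,1,0,25
Rajasthan,49,25,6,1,1,54
Sikkim,99,83,32,5,0,0
Tamil Nadu,98,79,26,3,0,0
Tripura,98,77,30,4,0,0
Uttar Pradesh,75,42,11,1,0,15
Uttaranchal,69,36,9,1,0,20
West Bengal,93,68,26,4,0,2
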