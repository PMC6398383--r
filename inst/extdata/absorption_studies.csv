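study_id,n,anemia_status,cereal,mean_abs,sd_abs
thankachan_2008_anemic,20,anemic,rice,17.5,11.4
thankachan_2008_normal,20,normal,rice,7.3,5.9
kalasuramath_2013_rice,15,anemic,rice,8.3,2.2
kalasuramath_2013_wheat,15,anemic,wheat,11.2,1.6
kalasuramath_2013_ragi,15,anemic,millet,4.6,1.9
kalasuramath_2013_normal,15,normal,rice,2.7,1.7
herter_aeberli_2016_ow,16,normal,rice,10.0,6.5
herter_aeberli_2016_nw,13,normal,rice,16.7,4.6
nair_2013,16,normal,rice,9.7,6.5
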