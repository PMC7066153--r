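measure,source,mean_patient,sd_patient,n_patient,mean_healthy,sd_healthy,n_healthy,d_printed
human_rating,,3.3,1.3,354,4.6,1.1,681,1.1
word_count,,48.7,22.4,354,65.2,21.4,681,0.8
common_types,human,16.4,6.8,354,26.7,8.1,681,1.4
common_types,generic_asr,14.4,6.5,354,25.4,7.9,681,1.5
common_types,custom_asr,16.5,6.5,354,26.7,7.9,681,1.4
wmd,human,1.7,0.5,354,1.3,0.4,681,-1.0
wmd,generic_asr,1.8,0.5,354,1.3,0.4,681,-1.2
wmd,custom_asr,1.7,0.4,354,1.3,0.4,681,-1.1
predicted_score,human,3.4,0.9,354,4.6,0.9,681,1.3
predicted_score,generic_asr,3.4,0.8,354,4.6,0.9,681,1.4
predicted_score,custom_asr,3.4,0.9,354,4.6,0.9,681,1.3
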