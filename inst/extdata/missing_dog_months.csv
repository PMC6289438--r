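dataset,dog_id,month
thoracic_gait,13103FN,2
thoracic_gait,13103FN,3
thoracic_gait,13103FN,4
thoracic_gait,13103FN,5
thoracic_gait,13103FN,11
thoracic_gait,13102MA,2
thoracic_gait,13102MA,3
thoracic_gait,13102MA,4
thoracic_gait,13102MA,5
thoracic_gait,13303MA,2
thoracic_gait,13303MA,3
thoracic_gait,13301MN,2
thoracic_gait,13301MN,3
clinical_score,13303MA,4
clinical_score,13401MA,2
locomotor_activity,13401MA,2
locomotor_activity,13401MA,3
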