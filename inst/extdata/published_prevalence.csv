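condition,expert_pos_paper,n_paper,expert_pos_mobile,n_mobile,chw_pos_paper,chw_pos_mobile
low_birth_weight,41,84,45,86,0,45
small,41,84,45,86,9,46
very_low_weight_lt1500,6,84,8,86,18,7
severe_weight_loss,21,84,21,86,14,20
moderate_weight_loss,18,84,18,86,22,17
poor_movement,3,84,3,86,34,4
convulsion_history,19,84,19,86,23,25
poor_feeding,52,84,52,86,35,47
severe_chest_indrawing,3,84,5,86,9,17
fast_breathing,18,84,15,86,9,2
umbilicus_red_or_pus,13,84,13,86,4,18
skin_pustules,0,84,0,86,2,6
jaundice_soles_or_body,9,84,10,86,18,23
eye_infection,0,84,0,86,2,5
fever,13,84,13,86,19,10
hypothermia,5,84,5,86,23,5
feeding_intolerance,7,84,6,86,22,12
breastfeeding_problems,32,84,32,86,62,32
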