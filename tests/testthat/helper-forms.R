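# Answer function reading truthfully off a case, for driving the form
# engine in tests (guided entry cannot record "not assessed", so
# unassessed tri-states resolve to the favourable answer).
mobile_answers_for <- function(case) {
  function(item, answers) {
    id <- item$id
    if (startsWith(id, "sign_")) {
      v <- case$signs[[sub("^sign_", "", id)]]
      return(if (identical(v, "yes")) "yes" else "no")
    }
    if (startsWith(id, "fi_")) {
      v <- case$feeding_intolerance[[sub("^fi_", "", id)]]
      return(if (identical(v, "yes")) "yes" else "no")
    }
    if (startsWith(id, "bf_")) {
      v <- case$breastfeeding[[sub("^bf_", "", id)]]
      return(if (identical(v, "no")) "no" else "yes")
    }
    switch(id,
      infant_id = case$infant_id,
      sex = case$sex,
      birth_datetime = case$birth_datetime,
      assessment_datetime = case$assessment_datetime,
      lmp_known = if (is.na(case$lmp_date)) "no" else "yes",
      lmp_date = case$lmp_date,
      birth_weight_known = if (is.na(case$birth_weight_g)) "no" else "yes",
      birth_weight_g = case$birth_weight_g,
      current_weight_g = case$current_weight_g,
      foot_length_mm = case$foot_length_mm,
      temperature_c = normalize_temperature(case$temperature, case$temperature_unit),
      breath_count_60s = case$breath_count_60s,
      kmc_counseled = "yes",
      skin_to_skin_hours = 4,
      stop("unexpected item: ", id)
    )
  }
}
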