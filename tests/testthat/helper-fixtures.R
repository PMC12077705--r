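# Fixtures built in code: tiny hand-assembled patients and tables used
# across the unit tests. Dates are anchored at a fixed origin so expected
# day offsets are easy to read.

d0 <- as.Date("2015-01-01")

make_patient <- function(id = "P1",
                         diagnosis = d0,
                         surgery = d0 + 14,
                         crt_end = d0 + 90,
                         clinical = NA,
                         year = 2015L,
                         followup_complete = TRUE) {
  data.frame(
    patient_id = id, diagnosis_date = diagnosis, surgery_date = surgery,
    crt_end_date = crt_end,
    clinical_progression_date = as.Date(clinical, origin = "1970-01-01"),
    treatment_year = year, followup_complete = followup_complete,
    stringsAsFactors = FALSE
  )
}

make_rx <- function(id = "P1", drug = "dexamethasone", brand = "",
                    dose = 4, route = "oral", date = d0 + 200) {
  data.frame(
    patient_id = id, drug_name = drug, brand_name = brand, dose_mg = dose,
    route = route, order_date = date, stringsAsFactors = FALSE
  )
}

make_report <- function(id = "P1", date = d0 + 200,
                        type = "MRI BRAIN-Perfusion (IP)",
                        text = "The examination is stable.") {
  data.frame(
    patient_id = id, report_date = date, document_type = type, text = text,
    stringsAsFactors = FALSE
  )
}

make_scan <- function(id = "P1", date = d0 + 200, ce = 10, ne = 5,
                      edema = 20) {
  data.frame(
    patient_id = id, scan_date = date, ce_tumor_cm3 = ce, ne_tumor_cm3 = ne,
    edema_cm3 = edema, stringsAsFactors = FALSE
  )
}

# A minimal 3-patient bundle exercising all four tables.
tiny_cohort <- function() {
  patients <- rbind(
    make_patient("A", clinical = d0 + 300),
    make_patient("B", clinical = NA),
    make_patient("C", clinical = d0 + 150)
  )
  gbm_cohort(
    patients,
    rbind(
      make_rx("A", date = d0 + 250), make_rx("B", drug = "temozolomide"),
      make_rx("C", date = d0 + 160)
    ),
    rbind(
      make_report("A"), make_report("B", date = d0 + 210),
      make_report("C", date = d0 + 120)
    ),
    rbind(
      make_scan("A", d0 + 20), make_scan("A", d0 + 150),
      make_scan("A", d0 + 240), make_scan("B", d0 + 20),
      make_scan("B", d0 + 150), make_scan("B", d0 + 240),
      make_scan("C", d0 + 20), make_scan("C", d0 + 150),
      make_scan("C", d0 + 240)
    )
  )
}

# Match-row constructor mirroring extract_matches() output, for testing the
# re-categorisation rule table directly.
make_match <- function(category = "progression", negated = FALSE,
                       historical = FALSE, hypothetical = FALSE,
                       family = FALSE, surgical = FALSE) {
  data.frame(
    surface_text = "x", matched_stem = "x", base_category = category,
    negated = negated, historical = historical, hypothetical = hypothetical,
    family = family, surgical = surgical, sentence_index = 1L,
    start = 0L, end = 1L, stringsAsFactors = FALSE
  )
}
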