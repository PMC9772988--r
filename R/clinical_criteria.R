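#' ADA diagnostic criterion for diabetes
#'
#' Applies the American Diabetes Association plasma-based diagnostic rule:
#' fasting plasma glucose (FPG) >= 126 mg/dL or HbA1c >= 6.5% (NGSP).  In the
#' absence of unequivocal hyperglycaemia a single abnormal result is not
#' diagnostic: confirmation in a second sample is required.
#'
#' @param fpg Fasting plasma glucose in mg/dL (fasting = no caloric intake for
#'   at least 8 h). May be `NA` if `hba1c` is supplied.
#' @param hba1c HbA1c in NGSP percent. May be `NA` if `fpg` is supplied.
#' @param second_sample_abnormal Logical; was the abnormal result confirmed in
#'   a second, separate sample?
#' @param unequivocal_hyperglycaemia Logical; unmistakable clinical
#'   hyperglycaemia, which waives the confirmation requirement.
#' @return Logical vector: does the subject meet the diagnostic criterion?
#' @examples
#' ada_diabetes(fpg = 126, hba1c = 5.5, second_sample_abnormal = TRUE)
#' ada_diabetes(fpg = 100, hba1c = 6.6, second_sample_abnormal = FALSE)
#' @export
ada_diabetes <- function(fpg = NA_real_, hba1c = NA_real_,
                         second_sample_abnormal = FALSE,
                         unequivocal_hyperglycaemia = FALSE) {
  n <- max(length(fpg), length(hba1c))
  fpg <- rep_len(fpg, n)
  hba1c <- rep_len(hba1c, n)
  second_sample_abnormal <- rep_len(second_sample_abnormal, n)
  unequivocal_hyperglycaemia <- rep_len(unequivocal_hyperglycaemia, n)
  if (any(is.na(fpg) & is.na(hba1c))) {
    abort("at least one of `fpg` or `hba1c` must be provided for every subject")
  }
  if (any(fpg <= 0, na.rm = TRUE) || any(hba1c <= 0, na.rm = TRUE)) {
    abort("`fpg` and `hba1c` must be positive")
  }
  threshold_met <- (!is.na(fpg) & fpg >= 126) | (!is.na(hba1c) & hba1c >= 6.5)
  threshold_met & (unequivocal_hyperglycaemia | second_sample_abnormal)
}

#' Ascertain incident type 2 diabetes at follow-up
#'
#' A subject free of diabetes at baseline is classified as an incident case
#' when either the ADA criterion ([ada_diabetes()]) is met on follow-up
#' laboratory samples, or a physician has recorded a diabetes diagnosis in the
#' medical record during follow-up.
#'
#' @param baseline A data frame (one row per subject) with baseline `fpg` and
#'   `hba1c` columns; used only to verify that nobody was diabetic at entry.
#' @param followup_fpg,followup_hba1c Follow-up laboratory values (mg/dL, %).
#' @param second_sample_abnormal Logical; follow-up confirmation sample
#'   abnormal.
#' @param physician_record_flag Logical; diabetes recorded in the medical
#'   record over the study period.
#' @param baseline_confirmed Logical; treat baseline labs as confirmed values
#'   when checking the exclusion rule (default `TRUE`).
#' @return Logical vector of incident-diabetes indicators.
#' @export
incident_t2d <- function(baseline, followup_fpg = NA_real_,
                         followup_hba1c = NA_real_,
                         second_sample_abnormal = FALSE,
                         physician_record_flag = FALSE,
                         baseline_confirmed = TRUE) {
  stopifnot(is.data.frame(baseline))
  if (!all(c("fpg", "hba1c") %in% names(baseline))) {
    abort("`baseline` must contain `fpg` and `hba1c` columns")
  }
  base_dm <- ada_diabetes(baseline$fpg, baseline$hba1c,
                          second_sample_abnormal = baseline_confirmed)
  if (any(base_dm)) {
    abort(paste0("subjects diabetic at baseline should have been excluded (rows ",
                 paste(which(base_dm), collapse = ", "), ")"))
  }
  ada_diabetes(followup_fpg, followup_hba1c, second_sample_abnormal) |
    rep_len(as.logical(physician_record_flag), nrow(baseline))
}

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `HOMA-IR = fasting insulin (uU/mL) x fasting glucose (mmol/L) / 22.5`.
#' Use [mgdl_to_mmol()] first when glucose is recorded in mg/dL.
#'
#' @param fasting_insulin Fasting serum insulin in uU/mL; must be positive.
#' @param fpg_mmol Fasting plasma glucose in mmol/L; must be positive.
#' @return Numeric HOMA-IR score.
#' @examples
#' homa_ir(10, mgdl_to_mmol(90))
#' @export
homa_ir <- function(fasting_insulin, fpg_mmol) {
  if (any(!is.finite(fasting_insulin)) || any(!is.finite(fpg_mmol)) ||
      any(fasting_insulin <= 0) || any(fpg_mmol <= 0)) {
    abort("`fasting_insulin` and `fpg_mmol` must be positive and finite")
  }
  fasting_insulin * fpg_mmol / 22.5
}

#' Glucose unit conversion
#'
#' mg/dL to mmol/L (and back) using the conventional molar factor 18.0.
#'
#' @param x Glucose concentration.
#' @return Converted concentration.
#' @export
mgdl_to_mmol <- function(x) x / 18

#' @rdname mgdl_to_mmol
#' @export
mmol_to_mgdl <- function(x) x * 18

#' Convert HbA1c between NGSP (%) and IFCC (mmol/mol) units
#'
#' Uses the NGSP/IFCC master equation `IFCC = (NGSP - 2.15) x 10.929`,
#' reported to one decimal as is conventional for IFCC units.
#'
#' @param hba1c_pct HbA1c in NGSP percent; must lie in (3, 20) except for the
#'   degenerate intercept value used in round-trip checks.
#' @param strict Validate the plausible-range constraint (default `TRUE`).
#' @return HbA1c in IFCC mmol/mol, rounded to 1 decimal.
#' @examples
#' hba1c_ngsp_to_ifcc(5.8) # 39.9
#' @export
hba1c_ngsp_to_ifcc <- function(hba1c_pct, strict = TRUE) {
  if (strict && any(hba1c_pct <= 3 | hba1c_pct >= 20, na.rm = TRUE)) {
    abort("`hba1c_pct` outside the plausible NGSP range (3, 20)")
  }
  round((hba1c_pct - 2.15) * 10.929, 1)
}

#' @rdname hba1c_ngsp_to_ifcc
#' @param hba1c_ifcc HbA1c in IFCC mmol/mol.
#' @export
hba1c_ifcc_to_ngsp <- function(hba1c_ifcc) {
  hba1c_ifcc / 10.929 + 2.15
}

#' ATP-III metabolic syndrome classification
#'
#' Evaluates the five Adult Treatment Panel III components with the printed
#' sex-specific cut-offs:
#' abdominal obesity (waist > 102 cm in males, > 88 cm in females);
#' hypertriglyceridaemia (triglycerides >= 150 mg/dL);
#' low HDL cholesterol (< 40 mg/dL males, < 50 mg/dL females);
#' high blood pressure (SBP >= 130 or DBP >= 85 mmHg, or current
#' antihypertensive medication); and
#' hyperglycaemia (FPG >= 110 mg/dL or current antidiabetic therapy).
#' Metabolic syndrome is the presence of at least three components.
#'
#' @param profiles Data frame with columns `sex` ("male"/"female"), `waist`
#'   (cm), `triglycerides` (mg/dL), `hdl` (mg/dL), `sbp`, `dbp` (mmHg),
#'   `antihypertensive_use` (logical), `fpg` (mg/dL) and optionally
#'   `antidiabetic_use` (logical, assumed `FALSE` when absent).
#' @return A tibble with one row per subject: the five component flags,
#'   `n_components` (0-5) and `metabolic_syndrome`.
#' @export
metabolic_syndrome <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  required <- c("sex", "waist", "triglycerides", "hdl", "sbp", "dbp",
                "antihypertensive_use", "fpg")
  missing_cols <- setdiff(required, names(profiles))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (col in required) {
    if (anyNA(profiles[[col]])) {
      abort(paste0("missing values in required field `", col, "`"))
    }
  }
  sex <- tolower(as.character(profiles$sex))
  if (!all(sex %in% c("male", "female"))) {
    abort('`sex` must be "male" or "female"')
  }
  male <- sex == "male"
  antidiabetic <- col_or(profiles, "antidiabetic_use", FALSE)
  flags <- tibble::tibble(
    subject_id = col_or(profiles, "subject_id", seq_len(nrow(profiles))),
    abdominal_obesity = ifelse(male, profiles$waist > 102, profiles$waist > 88),
    hypertriglyceridaemia = profiles$triglycerides >= 150,
    low_hdl = ifelse(male, profiles$hdl < 40, profiles$hdl < 50),
    high_bp = profiles$sbp >= 130 | profiles$dbp >= 85 |
      as.logical(profiles$antihypertensive_use),
    hyperglycaemia = profiles$fpg >= 110 | as.logical(antidiabetic)
  )
  flags$n_components <- rowSums(flags[, c("abdominal_obesity",
                                          "hypertriglyceridaemia", "low_hdl",
                                          "high_bp", "hyperglycaemia")])
  flags$metabolic_syndrome <- flags$n_components >= 3
  flags
}

#' Annotate a cohort table with derived clinical columns
#'
#' Table-in/table-out convenience: joins the ATP-III component flags
#' ([metabolic_syndrome()]), HOMA-IR ([homa_ir()]) and IFCC HbA1c
#' ([hba1c_ngsp_to_ifcc()]) onto a cohort table.
#'
#' @param cohort Cohort data frame with the columns required by
#'   [metabolic_syndrome()] plus `fasting_insulin` and `hba1c`.
#' @return The cohort as a tibble with `homa_ir`, `hba1c_ifcc` and the
#'   metabolic-syndrome columns appended.
#' @export
add_clinical_flags <- function(cohort) {
  flags <- metabolic_syndrome(cohort)
  out <- tibble::as_tibble(cohort)
  out$homa_ir <- homa_ir(cohort$fasting_insulin, mgdl_to_mmol(cohort$fpg))
  out$hba1c_ifcc <- hba1c_ngsp_to_ifcc(cohort$hba1c)
  keep <- setdiff(names(flags), "subject_id")
  out[keep] <- flags[keep]
  out
}
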