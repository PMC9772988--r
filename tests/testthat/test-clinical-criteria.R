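test_that("ADA diagnosis needs a threshold plus confirmation", {
  expect_true(ada_diabetes(fpg = 126, second_sample_abnormal = TRUE))
  expect_false(ada_diabetes(fpg = 100, hba1c = 5.5,
                            second_sample_abnormal = TRUE))
  # one abnormal HbA1c without confirmation is not diagnostic
  expect_false(ada_diabetes(hba1c = 6.6, second_sample_abnormal = FALSE))
  expect_true(ada_diabetes(hba1c = 6.6, unequivocal_hyperglycaemia = TRUE))
  expect_error(ada_diabetes(fpg = -1), "positive")
  expect_error(ada_diabetes(), "at least one")
})

test_that("incident diabetes combines follow-up labs and record review", {
  base <- tibble::tibble(fpg = c(90, 100), hba1c = c(5.2, 5.6))
  expect_equal(incident_t2d(base, followup_fpg = c(95, 100),
                            physician_record_flag = c(TRUE, FALSE)),
               c(TRUE, FALSE))
  expect_equal(incident_t2d(base, followup_fpg = c(130, 100),
                            second_sample_abnormal = c(TRUE, FALSE)),
               c(TRUE, FALSE))
  diabetic_base <- tibble::tibble(fpg = 130, hba1c = 6.8)
  expect_error(incident_t2d(diabetic_base, followup_fpg = 100),
               "excluded")
})

test_that("HOMA-IR follows the insulin x glucose / 22.5 formula", {
  expect_equal(homa_ir(22.5, 1.0), 1.0)
  expect_equal(homa_ir(10, mgdl_to_mmol(90)), 10 * 5 / 22.5)
  expect_error(homa_ir(0, 5), "positive")
  expect_error(homa_ir(10, -2), "positive")
  # bilinear: scaling either argument scales the score
  ins <- runif(20, 2, 30)
  glu <- runif(20, 3, 8)
  expect_equal(homa_ir(3 * ins, glu), 3 * homa_ir(ins, glu))
  expect_equal(homa_ir(ins, 2 * glu), 2 * homa_ir(ins, glu))
})

test_that("NGSP/IFCC conversion reproduces the master equation", {
  expect_equal(hba1c_ngsp_to_ifcc(5.8), 39.9)
  expect_equal(hba1c_ngsp_to_ifcc(6.5), 47.5)
  expect_equal(hba1c_ngsp_to_ifcc(2.15, strict = FALSE), 0.0)
  expect_error(hba1c_ngsp_to_ifcc(25), "range")
  # affine and invertible: round trip below reporting precision
  x <- seq(4, 12, by = 0.1)
  back <- hba1c_ifcc_to_ngsp(hba1c_ngsp_to_ifcc(x))
  expect_lt(max(abs(back - x)), 0.05)
})

test_that("ATP-III components use the printed sex-specific cut-offs", {
  male3 <- tibble::tibble(sex = "male", waist = 103, triglycerides = 150,
                          hdl = 39, sbp = 120, dbp = 80,
                          antihypertensive_use = FALSE, fpg = 100)
  f <- metabolic_syndrome(male3)
  expect_equal(f$n_components, 3)
  expect_true(f$metabolic_syndrome)

  female0 <- tibble::tibble(sex = "female", waist = 80, triglycerides = 100,
                            hdl = 60, sbp = 110, dbp = 70,
                            antihypertensive_use = FALSE, fpg = 90)
  expect_equal(metabolic_syndrome(female0)$n_components, 0)

  # boundary audit: waist and HDL strict, TG/BP/FPG inclusive
  boundary <- tibble::tibble(sex = "male", waist = 102, triglycerides = 149,
                             hdl = 40, sbp = 129, dbp = 84,
                             antihypertensive_use = FALSE, fpg = 109)
  expect_equal(metabolic_syndrome(boundary)$n_components, 0)
  just_over <- tibble::tibble(sex = "male", waist = 102.1,
                              triglycerides = 150, hdl = 39.9, sbp = 130,
                              dbp = 70, antihypertensive_use = FALSE,
                              fpg = 110)
  expect_equal(metabolic_syndrome(just_over)$n_components, 5)

  # medication flags satisfy the pressure / glycaemia components alone
  treated <- tibble::tibble(sex = "female", waist = 80, triglycerides = 100,
                            hdl = 60, sbp = 110, dbp = 70,
                            antihypertensive_use = TRUE, fpg = 90,
                            antidiabetic_use = TRUE)
  tf <- metabolic_syndrome(treated)
  expect_true(tf$high_bp)
  expect_true(tf$hyperglycaemia)

  expect_error(metabolic_syndrome(male3[, -2]), "waist")
})

test_that("metabolic syndrome is monotone under worsening components", {
  set.seed(11)
  for (i in 1:25) {
    prof <- tibble::tibble(
      sex = sample(c("male", "female"), 1),
      waist = runif(1, 60, 130), triglycerides = runif(1, 50, 400),
      hdl = runif(1, 25, 90), sbp = runif(1, 95, 180),
      dbp = runif(1, 55, 110), antihypertensive_use = runif(1) < 0.3,
      fpg = runif(1, 70, 135)
    )
    before <- metabolic_syndrome(prof)$n_components
    worse <- prof
    worse$waist <- worse$waist + 20
    worse$triglycerides <- worse$triglycerides + 100
    worse$hdl <- worse$hdl - 15
    worse$sbp <- worse$sbp + 25
    worse$fpg <- worse$fpg + 30
    after <- metabolic_syndrome(worse)$n_components
    expect_gte(after, before)
  }
})

test_that("add_clinical_flags annotates a cohort consistently", {
  co <- read_cohort_csv(system.file("extdata", "synthetic_cohort_n60.csv",
                                    package = "cgmrisk"))
  out <- add_clinical_flags(co)
  expect_equal(nrow(out), nrow(co))
  expect_equal(out$homa_ir,
               homa_ir(co$fasting_insulin, mgdl_to_mmol(co$fpg)))
  expect_equal(out$metabolic_syndrome, out$n_components >= 3)
  expect_equal(out$n_components,
               rowSums(out[, c("abdominal_obesity", "hypertriglyceridaemia",
                               "low_hdl", "high_bp", "hyperglycaemia")]))
})
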