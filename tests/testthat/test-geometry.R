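test_that("side classification dichotomizes at the median with >= meaning large", {
  # men right-side reference medians force each category
  expect_equal(as.character(classify_side(0.70, 8.20, 0.663, 8.092)), "BOTH")
  expect_equal(as.character(classify_side(0.60, 7.00, 0.663, 8.092)), "NEITHER")
  expect_equal(as.character(classify_side(0.60, 8.20, 0.663, 8.092)), "DIA_ONLY")
  # a value exactly at the median is large
  expect_equal(as.character(classify_side(0.663, 8.00, 0.663, 8.092)), "IMT_ONLY")
  expect_equal(as.character(classify_side(0.663, 8.092, 0.663, 8.092)), "BOTH")
  expect_error(classify_side(NA, 8, 0.663, 8.092), "missing")
  expect_error(classify_side(-0.1, 8, 0.663, 8.092), "positive")
})

test_that("the 16 ordered pairs map onto phenotypes 1..10 symmetrically and surjectively", {
  lv <- geometry_levels()
  grid <- expand.grid(r = lv, l = lv, stringsAsFactors = FALSE)
  ids <- bilateral_phenotype(grid$r, grid$l)
  expect_setequal(unique(ids), 1:10)
  # symmetry over every pair
  expect_equal(ids, bilateral_phenotype(grid$l, grid$r))
  # spot checks of the defined mapping
  expect_equal(bilateral_phenotype("BOTH", "BOTH"), 1L)
  expect_equal(bilateral_phenotype("BOTH", "IMT_ONLY"), 2L)
  expect_equal(bilateral_phenotype("DIA_ONLY", "IMT_ONLY"), 6L)
  expect_equal(bilateral_phenotype("IMT_ONLY", "NEITHER"), 7L)
  expect_equal(bilateral_phenotype("NEITHER", "NEITHER"), 10L)
  expect_error(bilateral_phenotype("BOTH", "HUGE"), "invalid")
})

test_that("combined-set membership matches the defining id lists", {
  expect_setequal(combined_membership(1),
                  c("IMT_BILAT", "DIA_BILAT", "ANY_BILAT",
                    "SAME_SIDE_BOTH", "ANY_IMT", "ANY_DIA"))
  expect_equal(combined_membership(10), character(0))
  expect_equal(combined_membership(9), "ANY_DIA")
  expect_setequal(combined_membership(5), c("IMT_BILAT", "ANY_BILAT", "ANY_IMT"))
  expect_error(combined_membership(11), "1..10")
})

test_that("medians follow the midpoint convention and name empty strata in errors", {
  co <- data.frame(sex = rep("F", 4),
                   r_imt_mm = c(0.60, 0.62, 0.66, 0.70),
                   l_imt_mm = c(1, 2, 3, 4), r_dia_mm = 7:10, l_dia_mm = 7:10)
  expect_error(compute_medians(co), "male")  # men stratum empty, named in error
  co_m <- rbind(co, transform(co, sex = "M"))
  med2 <- compute_medians(co_m)
  expect_equal(median_for(med2, "F", "R", "IMT"), 0.64)  # even-n midpoint
  expect_equal(median_for(med2, "F", "L", "IMT"), 2.5)
  co3 <- data.frame(sex = rep(c("M", "F"), each = 3), r_imt_mm = c(1, 2, 3, 1, 1, 1),
                    l_imt_mm = 1, r_dia_mm = 1, l_dia_mm = 1)
  expect_equal(median_for(compute_medians(co3), "M", "R", "IMT"), 2)
})

test_that("compute_medians errors when a stratum has no usable values", {
  co <- data.frame(sex = c("F", "M"), r_imt_mm = c(NA_real_, 1), l_imt_mm = 1,
                   r_dia_mm = 1, l_dia_mm = 1)
  expect_error(compute_medians(co), "female RCCA IMT")
})

test_that("phenotype ids partition random cohorts and median splits are balanced", {
  for (seed in c(3, 17, 29)) {
    co <- small_cohort(n = 501, seed = seed)  # odd n: unique median subject
    cl <- classify_cohort(co)
    expect_equal(sum(table(factor(cl$phenotype_id, levels = 1:10))), nrow(cl))
    expect_false(anyNA(cl$phenotype_id))
    # continuous tie-free data: "large" count is ceiling(n/2) per parameter
    for (sx in c("M", "F")) {
      sub <- cl[cl$sex == sx, ]
      med <- median_for(compute_medians(co), sx, "R", "IMT")
      expect_equal(sum(sub$r_imt_mm >= med), ceiling(nrow(sub) / 2))
    }
  }
})

test_that("phenotype tabulation counts sum to stratum sizes and a single subject gives one row", {
  co <- small_cohort(n = 800, seed = 5)
  cl <- classify_cohort(co)
  tab <- tabulate_phenotypes(cl)
  for (sx in unique(cl$sex))
    expect_equal(sum(tab$n[tab$sex == sx]), sum(cl$sex == sx))
  expect_equal(sum(tab$n_events), sum(cl$event))
  one <- cl[1, ]
  t1 <- tabulate_phenotypes(one)
  expect_equal(sum(t1$n), 1L)
  expect_equal(sum(t1$n > 0), 1L)
})

test_that("classification against an external median table honours the >= rule", {
  med <- reference_medians()
  co <- data.frame(sex = "M",
                   r_imt_mm = 0.663, r_dia_mm = 8.092,  # exact ties -> large
                   l_imt_mm = 0.60, l_dia_mm = 7.00)
  cl <- classify_cohort(co, medians = med)
  expect_equal(as.character(cl$r_geometry), "BOTH")
  expect_equal(as.character(cl$l_geometry), "NEITHER")
  expect_equal(cl$phenotype_id, 4L)
})
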