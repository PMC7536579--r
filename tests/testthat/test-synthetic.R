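# synthetic_data: zero-noise limits, determinism, reference battery,
# registry simulation, no label leakage, batch-effect monotonicity.

zero_noise_profiles <- function(assays = c("TA_HeLa_ALB", "TA_INS1_P2",
                                           "PE", "NUC_LOC")) {
  default_class_profiles(assays, replicate_sd = 0)
}

test_that("zero-noise datasets reproduce class means exactly", {
  spec <- panel_spec(n_variants_per_lab = 6L, n_replicates = 3L,
                     shared_variant_count = 2L, lab_effect_sd = 0,
                     seed = 3L)
  panel <- generate_panel(spec, zero_noise_profiles())
  ds <- as.data.frame(panel$dataset)
  truth <- panel$truth
  profs <- zero_noise_profiles()
  for (i in seq_len(nrow(ds))) {
    cls <- truth$class_label[truth$variant == ds$variant[i]]
    expect_equal(ds$value[i], profs[[cls]]$mean_activity[[ds$assay[i]]],
                 tolerance = 1e-12)
  }
  # in particular every DAMAGING TA replicate is exactly 0.30
  dam <- truth$variant[truth$class_label == "DAMAGING"]
  ta <- ds$value[ds$variant %in% dam & grepl("^TA", ds$assay)]
  if (length(ta)) expect_true(all(ta == 0.3))
})

test_that("same spec and seed give byte-identical datasets", {
  spec <- panel_spec(seed = 42L)
  p1 <- generate_panel(spec)
  p2 <- generate_panel(spec)
  expect_identical(p1, p2)
  f1 <- tempfile(); f2 <- tempfile()
  write_functional_table(p1$dataset, f1)
  write_functional_table(p2$dataset, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed changes the payload but not the schema
  p3 <- generate_panel(panel_spec(seed = 43L))
  expect_false(identical(as.data.frame(p1$dataset), as.data.frame(p3$dataset)))
  expect_identical(names(p1$dataset), names(p3$dataset))
})

test_that("sample means of WT_LIKE TA replicates sit within 3 SE of the mean", {
  spec <- panel_spec(seed = 1L)   # default conditions
  profs <- default_class_profiles(spec$assay_variables)
  panel <- generate_panel(spec, profs)
  ds <- as.data.frame(panel$dataset)
  wt <- panel$truth$variant[panel$truth$class_label == "WT_LIKE"]
  for (lab in spec$labs) {
    for (a in c("TA_HeLa_ALB", "TA_INS1_P2")) {
      vals <- ds$value[ds$variant %in% wt & ds$lab == lab & ds$assay == a]
      lf <- hnf1astrat:::lab_factors(spec)[lab, a]
      mu <- profs$WT_LIKE$mean_activity[[a]] * lf
      # replicate noise is mean-one log-normal with sdlog s:
      # sd of one replicate = mu * sqrt(exp(s^2) - 1)
      s <- profs$WT_LIKE$replicate_sd[[a]]
      se <- mu * sqrt(exp(s^2) - 1) / sqrt(length(vals))
      expect_lt(abs(mean(vals) - mu), 3 * se)
    }
  }
})

test_that("reference battery has the documented roles and ordering", {
  spec <- panel_spec(seed = 5L)
  refs <- generate_references(spec, zero_noise_profiles())
  ann <- refs$annotations
  expect_equal(sum(ann$reference_role == "WILD_TYPE"), 2L)
  expect_gte(sum(ann$reference_role == "MODY_REFERENCE"), 6L)
  expect_gte(sum(ann$reference_role == "T2D_REFERENCE"), 1L)
  # every lab measures the full battery
  ds <- as.data.frame(refs$dataset)
  for (lab in spec$labs) {
    expect_setequal(unique(ds$variant[ds$lab == lab]), ann$variant)
  }
  # zero-noise: MODY references are lower than wild-type on TA_HeLa_ALB
  ta <- ds[ds$assay == "TA_HeLa_ALB" & ds$lab == spec$labs[1], ]
  wt_val <- ta$value[ta$variant %in% ann$variant[ann$reference_role == "WILD_TYPE"]]
  mody_val <- ta$value[ta$variant %in% ann$variant[ann$reference_role == "MODY_REFERENCE"]]
  expect_true(all(mody_val < min(wt_val)))
})

test_that("registry simulation respects class-conditional rules and seed", {
  spec <- panel_spec(seed = 9L)
  panel <- generate_panel(spec)
  reg0 <- generate_registry(panel$truth, seed = 9L,
                            misclassification_rate = 0)
  dam <- panel$truth$variant[panel$truth$class_label == "DAMAGING"]
  expect_true(all(reg0$original_class[reg0$variant %in% dam] %in% 4:5))
  # damaging variants are ultra-rare by default (allele count <= 2)
  expect_true(all(reg0$gnomad_count[reg0$variant %in% dam] <= 2L))
  # reproducible under the same seed
  expect_identical(reg0, generate_registry(panel$truth, seed = 9L,
                                           misclassification_rate = 0))
  expect_error(generate_registry(data.frame(variant = "v",
                                            class_label = NA_character_)),
               "labels")
})

test_that("truth labels never leak into the dataset payload", {
  panel <- generate_panel(panel_spec(seed = 2L))
  ds <- as.data.frame(panel$dataset)
  expect_false(any(c("class_label", "truth") %in% names(ds)))
  expect_false(any(unlist(ds[c("variant", "lab", "assay")]) %in%
                     c("WT_LIKE", "INTERMEDIATE", "DAMAGING")))
})

test_that("between-lab variance of shared variants increases with lab_effect_sd", {
  shared_lab_var <- function(lab_sd) {
    vs <- vapply(1:6, function(s) {
      spec <- panel_spec(n_variants_per_lab = 10L, shared_variant_count = 5L,
                         lab_effect_sd = lab_sd, seed = s)
      panel <- generate_panel(spec)
      ds <- as.data.frame(panel$dataset)
      shared <- names(which(table(unique(ds[c("variant", "lab")])$variant) == 2L))
      agg <- stats::aggregate(value ~ variant + lab + assay,
                              ds[ds$variant %in% shared, ], mean)
      mean(tapply(agg$value, paste(agg$variant, agg$assay),
                  stats::var), na.rm = TRUE)
    }, 0)
    mean(vs)
  }
  v <- vapply(c(0, 0.15, 0.5), shared_lab_var, 0)
  expect_true(all(diff(v) > 0))
})

test_that("invalid panel specifications are rejected", {
  expect_error(panel_spec(n_variants_per_lab = 0L), "positive")
  expect_error(panel_spec(n_replicates = 0L), "positive")
  expect_error(panel_spec(shared_variant_count = 50L,
                          n_variants_per_lab = 40L), "shared_variant_count")
  expect_error(panel_spec(assay_variables = character()), "non-empty")
})
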