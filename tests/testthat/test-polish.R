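# polish: replicate aggregation, EMSA handling, position scores,
# standardization properties.

test_that("replicate aggregation averages (or medians) per cell", {
  expect_equal(unname(aggregate_replicates(toy_functional(c(0.8, 1.0, 1.2)))[1, 1]),
               1.0)
  expect_equal(unname(aggregate_replicates(toy_functional(0.7))[1, 1]), 0.7)
  expect_equal(unname(aggregate_replicates(toy_functional(c(0.1, 1.0, 1.1)),
                                           method = "median")[1, 1]), 1.0)
  counts <- attr(aggregate_replicates(toy_functional(c(0.8, 1.0, 1.2))),
                 "n_replicates")
  expect_equal(unname(counts[1, 1]), 3L)
})

test_that("aggregation enforces format level and single-lab input", {
  raw <- functional_dataset(data.frame(variant = "v", lab = "Oxford",
                                       assay = "TA", replicate = 1L,
                                       value = 100), "RAW")
  expect_error(aggregate_replicates(raw), "CONTROL_NORMALIZED")
  two_labs <- functional_dataset(data.frame(variant = "v",
                                            lab = c("Oxford", "Bergen"),
                                            assay = "TA", replicate = 1L,
                                            value = c(1, 2)))
  expect_error(aggregate_replicates(two_labs), "separately")
})

test_that("EMSA variables are dropped, others untouched", {
  df <- expand.grid(variant = c("a", "b"), lab = "Oxford",
                    assay = c("TA_HeLa_ALB", "EMSA", "DNA_binding", "PE"),
                    replicate = 1:2, stringsAsFactors = FALSE)
  df$value <- seq_len(nrow(df))
  ds <- functional_dataset(df)
  out <- drop_emsa(ds)
  expect_setequal(unique(out$assay), c("TA_HeLa_ALB", "PE"))
  # no-op without EMSA, including on an empty dataset
  expect_identical(as.data.frame(drop_emsa(out)), as.data.frame(out))
  empty <- functional_dataset(df[0, ])
  expect_equal(nrow(drop_emsa(empty)), 0L)
})

test_that("EMSA candidates follow the domain / low-activity filter", {
  ann <- variant_annotation(data.frame(
    variant = c("v131", "v500a", "v500b", "v_missing"),
    residue = c(131L, 500L, 500L, 500L),
    exon = c(3L, 8L, 8L, 8L),
    gnomad_count = NA_integer_, reference_role = "NONE", lab = "Oxford"))
  ta <- data.frame(variant = c("v131", "v500a", "v500b"),
                   TA_HeLa_ALB = c(0.9, 0.40, 0.90))
  out <- emsa_candidates(ann, ta)
  expect_true(out$selected[out$variant == "v131"])    # in DNA-binding domain
  expect_true(out$selected[out$variant == "v500a"])   # TA < 50%
  expect_false(out$selected[out$variant == "v500b"])
  expect_true(out$ta_missing[out$variant == "v_missing"])
})

test_that("position scores follow the exon and residue bands", {
  ann <- variant_annotation(data.frame(
    variant = c("early", "exon7", "liver", "dbd", "ta_dom"),
    residue = c(100L, 450L, 526L, 131L, 300L),
    exon = c(2L, 7L, 9L, 3L, 5L),
    gnomad_count = NA_integer_, reference_role = "NONE", lab = "x"))
  sc <- assign_position_scores(ann)
  expect_equal(sc$isoform_band[sc$variant == "liver"], "LIVER_DOMINANT")
  expect_equal(sc$isoform_band[sc$variant == "exon7"], "TWO_ISOFORMS")
  expect_equal(sc$isoform_band[sc$variant == "early"], "ALL_ISOFORMS")
  expect_equal(sc$domain_band[sc$variant == "dbd"], "DNA_BINDING")
  expect_equal(sc$domain_band[sc$variant == "ta_dom"], "TRANSACTIVATION")
  expect_equal(sc$isoform_score[sc$variant == "early"], 3)
  expect_equal(sc$domain_score[sc$variant == "dbd"], 2)
  # configurable score maps
  sc2 <- assign_position_scores(ann, default_position_scores(all_isoforms = 10))
  expect_equal(sc2$isoform_score[sc2$variant == "early"], 10)
})

test_that("polish standardizes all columns and is affine invariant", {
  panel <- generate_panel(panel_spec(n_variants_per_lab = 12L,
                                     shared_variant_count = 0L, seed = 4L))
  ds <- panel$dataset
  sub <- functional_dataset(as.data.frame(ds)[ds$lab == "Oxford", ],
                            "CONTROL_NORMALIZED")
  pol <- polish_dataset(sub, panel$annotations)
  expect_equal(ncol(pol), 6L)   # 4 assay variables + 2 scores
  expect_false(any(grepl("emsa", colnames(pol), ignore.case = TRUE)))
  expect_lt(max(abs(colMeans(pol))), 1e-9)
  expect_lt(max(abs(apply(pol, 2, stats::sd) - 1)), 1e-9)
  expect_equal(rownames(pol), sort(rownames(pol)))

  # per-column affine rescaling of the aggregated data leaves the
  # standardized matrix unchanged: scale one assay by a positive factor
  df <- as.data.frame(sub)
  df$value[df$assay == "PE"] <- df$value[df$assay == "PE"] * 7
  pol2 <- polish_dataset(functional_dataset(df, "CONTROL_NORMALIZED"),
                         panel$annotations)
  expect_equal(unclass(pol2)[, ], unclass(pol)[, ], tolerance = 1e-9)

  # idempotence: de-standardize then re-polish the aggregated values
  back <- sweep(sweep(unclass(pol)[, 1:4], 2, attr(pol, "scale")[1:4], "*"),
                2, attr(pol, "center")[1:4], "+")
  long <- do.call(rbind, lapply(colnames(back), function(a) {
    data.frame(variant = rownames(back), lab = "Oxford", assay = a,
               replicate = 1L, value = back[, a])
  }))
  pol3 <- polish_dataset(functional_dataset(long, "CONTROL_NORMALIZED"),
                         panel$annotations)
  expect_equal(unclass(pol3)[, ], unclass(pol)[, ], tolerance = 1e-9)
})

test_that("polish rejects constant columns, missing annotations, wrong level", {
  ds <- functional_dataset(data.frame(
    variant = rep(c("p.Ala97Val", "p.Glu508Lys"), each = 2),
    lab = "Oxford",
    assay = rep(c("TA_HeLa_ALB", "PE"), 2),
    replicate = 1L,
    value = c(1, 5, 1, 7)))   # TA column constant across variants
  ann <- variant_annotation(data.frame(
    variant = c("p.Ala97Val", "p.Glu508Lys"), residue = c(97L, 508L),
    exon = c(2L, 8L), gnomad_count = NA_integer_,
    reference_role = "NONE", lab = "Oxford"))
  expect_error(polish_dataset(ds, ann), "TA_HeLa_ALB")
  expect_error(polish_dataset(ds, ann[1, ]), "missing annotation")
  wt_norm <- functional_dataset(as.data.frame(ds), "WT_NORMALIZED")
  expect_error(polish_dataset(wt_norm, ann), "CONTROL_NORMALIZED")
})
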