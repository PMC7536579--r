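# annotate_classify: zone annotation, frequency bands, rule engine,
# registry impact arithmetic.

test_that("zones follow reference membership, conflicts stay MIXED", {
  assignment <- c(WT_Ile27 = 1L, WT_Leu27 = 1L, v1 = 1L,
                  "p.Glu508Lys" = 2L, v2 = 2L,
                  "p.Pro112Leu" = 3L, v3 = 3L,
                  v4 = 4L)
  refs <- data.frame(
    variant = c("WT_Ile27", "WT_Leu27", "p.Glu508Lys", "p.Pro112Leu"),
    reference_role = c("WILD_TYPE", "WILD_TYPE", "T2D_REFERENCE",
                       "MODY_REFERENCE"))
  pts <- rbind(WT_Ile27 = c(0, 0), WT_Leu27 = c(0.2, 0), v1 = c(0.1, 0.1),
               "p.Glu508Lys" = c(3, 0), v2 = c(3.1, 0),
               "p.Pro112Leu" = c(6, 0), v3 = c(6.1, 0),
               v4 = c(6.5, 0.4))
  z <- annotate_zones(assignment, refs, points = pts)
  expect_equal(z$zone[z$cluster == 1L], "BENIGN")
  expect_equal(z$zone[z$cluster == 2L], "INTERMEDIATE_T2D_RISK")
  expect_equal(z$zone[z$cluster == 3L], "DAMAGING_MODY")
  # reference-free cluster 4 inherits from its nearest annotated centroid
  expect_equal(z$zone[z$cluster == 4L], "DAMAGING_MODY")
  expect_true(z$inherited[z$cluster == 4L])
  expect_false(any(z$inherited[z$cluster != 4L]))

  # WT and MODY in one cluster is MIXED, never silently resolved
  mixed <- annotate_zones(c(WT_Ile27 = 1L, "p.Pro112Leu" = 1L), refs)
  expect_equal(mixed$zone, "MIXED")
  expect_error(annotate_zones(c(a = 1L), refs), "reference")
})

test_that("frequency bands partition counts at the documented thresholds", {
  expect_equal(frequency_band(c(0L, 2L, 3L, 33L, 121L, 122L, 5000L)),
               c("MODY_COMPATIBLE", "MODY_COMPATIBLE", "LOW_FREQ_T2D",
                 "LOW_FREQ_T2D", "LOW_FREQ_T2D", "ABOVE_LOW_FREQ",
                 "ABOVE_LOW_FREQ"))
  expect_error(frequency_band(-1L), "non-negative")
  # allele fractions stand in where counts are missing
  expect_equal(frequency_band(NA_integer_, af = 5e-6), "MODY_COMPATIBLE")
  expect_equal(frequency_band(NA_integer_, af = 1e-4), "LOW_FREQ_T2D")
  expect_equal(frequency_band(NA_integer_, af = 1e-3), "ABOVE_LOW_FREQ")
})

test_that("rule engine reproduces the three worked examples", {
  rows <- data.frame(
    variant = c("p.Asn62Ser", "p.Ala276Asp", "p.Asp526Asn"),
    original_class = c(4L, 4L, 4L),
    zone = c("BENIGN", "DAMAGING_MODY", "DAMAGING_MODY"),
    band = c("LOW_FREQ_T2D", "MODY_COMPATIBLE", "LOW_FREQ_T2D"),
    exon = c(2L, 4L, 8L),
    co_occurring_pathogenic = FALSE)
  out <- reclassify(rows)
  # benign-zone class 4 with count 33 -> VUS/likely benign (R1)
  expect_equal(out$proposed_class[1], 3L)
  expect_equal(out$fired_rule[1], "R1")
  # ultra-rare damaging-zone early-exon variant retained as pathogenic (R5)
  expect_equal(out$proposed_class[2], 4L)
  expect_equal(out$status[2], "SUPPORTED")
  expect_false(out$changed[2])
  # liver-isoform damaging variant seen 5x in gnomAD downgraded (R2)
  expect_equal(out$proposed_class[3], 3L)
  expect_equal(out$fired_rule[3], "R2")
})

test_that("MIXED zones and missing attributes abstain", {
  rows <- data.frame(
    variant = c("m1", "m2"),
    original_class = c(4L, NA),
    zone = c("MIXED", "BENIGN"),
    band = "LOW_FREQ_T2D", exon = 3L,
    co_occurring_pathogenic = FALSE)
  out <- reclassify(rows)
  expect_true(all(is.na(out$proposed_class)))
  expect_true(all(out$status == "UNREVIEWED"))
})

test_that("the engine is pure and never upgrades toward pathogenic", {
  set.seed(77)
  rows <- data.frame(
    variant = sprintf("v%03d", 1:200),
    original_class = sample(1:5, 200, replace = TRUE),
    zone = sample(c("BENIGN", "INTERMEDIATE_T2D_RISK", "DAMAGING_MODY",
                    "MIXED"), 200, replace = TRUE),
    band = sample(c("MODY_COMPATIBLE", "LOW_FREQ_T2D", "ABOVE_LOW_FREQ"),
                  200, replace = TRUE),
    exon = sample(1:10, 200, replace = TRUE),
    co_occurring_pathogenic = sample(c(TRUE, FALSE), 200, replace = TRUE))
  out1 <- reclassify(rows)
  out2 <- reclassify(rows)
  expect_identical(out1, out2)   # pure function of its inputs
  reviewed <- !is.na(out1$proposed_class)
  expect_true(all(out1$proposed_class[reviewed] <=
                    out1$original_class[reviewed]))
  # the trace names every rule and the fired one is consistent
  expect_true(all(grepl("R1=.*R2=.*R3=.*R4=.*R5=", out1$trace[reviewed])))
  fired_r1 <- out1$fired_rule == "R1" & reviewed
  expect_true(all(grepl("R1=TRUE", out1$trace[fired_r1])))
})

test_that("registry impact arithmetic matches the printed percentages", {
  mk <- function(n_overlap, n_changed) {
    data.frame(variant = sprintf("v%d", seq_len(n_overlap)),
               original_class = 4L,
               proposed_class = c(rep(3L, n_changed),
                                  rep(4L, n_overlap - n_changed)),
               changed = c(rep(TRUE, n_changed),
                           rep(FALSE, n_overlap - n_changed)))
  }
  uk <- registry_report(mk(31, 7), 162, "UK")
  expect_equal(uk$pct_of_registry_rounded, 4)
  expect_equal(uk$pct_of_overlap_rounded, 23)
  expect_equal(uk$pct_of_registry, 100 * 7 / 162)
  no <- registry_report(mk(19, 5), 53, "NORWAY")
  expect_equal(no$pct_of_registry_rounded, 9)
  expect_equal(no$pct_of_overlap_rounded, 26)
  zero <- registry_report(mk(10, 0), 50)
  expect_equal(zero$pct_of_registry, 0)
  expect_equal(zero$pct_of_overlap, 0)
  expect_error(registry_report(mk(31, 7), 30), "smaller")
})
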