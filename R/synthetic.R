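# Synthetic two-laboratory assay panels with known latent classes.
#
# The generator emulates the two-center study design: each laboratory
# measures its own set of exome-detected variants plus a shared benchmark
# subset and a common battery of reference variants (two wild-type
# backgrounds, MODY-positive controls, type 2 diabetes risk controls).
# Readouts are strictly positive luciferase-style ratios, so both replicate
# noise and the laboratory batch effect are multiplicative log-normal.

CLASS_LABELS <- c("WT_LIKE", "INTERMEDIATE", "DAMAGING")

DEFAULT_ASSAYS <- c("TA_HeLa_ALB", "TA_INS1_P2", "PE", "NUC_LOC")

# Expand one root seed into independent named substreams so panel,
# references and registry are independently reproducible.
derive_seeds <- function(seed, streams) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% 2147483647L)
  s <- sample.int(2147483646L, length(streams))
  names(s) <- streams
  s
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  code
}

#' Latent class profile for the synthetic generator
#'
#' Expected assay readouts for one latent functional class, expressed as
#' fraction of wild-type (wild-type is 1.0 on every variable).
#'
#' @param class_label one of `"WT_LIKE"`, `"INTERMEDIATE"`, `"DAMAGING"`.
#' @param mean_activity named numeric vector, one entry per assay variable;
#'   all entries must be >= 0.
#' @param replicate_sd multiplicative replicate noise (sdlog of a mean-one
#'   log-normal); scalar or named per assay variable; must be > 0 (use the
#'   zero-noise limit via a tiny value or `replicate_sd = 0` which is allowed
#'   for exact-limit checks).
#' @param prevalence probability of the class in the panel.
#' @return an object of class `class_profile`.
#' @export
class_profile <- function(class_label, mean_activity, replicate_sd = 0.15,
                          prevalence = 1 / 3) {
  class_label <- match.arg(class_label, CLASS_LABELS)
  stopifnot(is.numeric(mean_activity), !is.null(names(mean_activity)),
            all(mean_activity >= 0), is.numeric(replicate_sd),
            all(replicate_sd >= 0), prevalence >= 0, prevalence <= 1)
  if (length(replicate_sd) == 1L) {
    replicate_sd <- stats::setNames(rep(replicate_sd, length(mean_activity)),
                                    names(mean_activity))
  }
  stopifnot(setequal(names(replicate_sd), names(mean_activity)))
  structure(list(class_label = class_label,
                 mean_activity = mean_activity,
                 replicate_sd = replicate_sd[names(mean_activity)],
                 prevalence = prevalence),
            class = "class_profile")
}

#' Default class profiles
#'
#' Class means are anchored to the printed transactivation activity ranges
#' (roughly 30%-110% of wild-type): wild-type-like variants sit at 1.0 on
#' every variable, intermediate variants at 0.6 of wild-type transactivation
#' (0.8 for protein expression and nuclear localization), and damaging
#' variants at 0.3 transactivation (0.5 protein expression and nuclear
#' localization). Default replicate noise is assay specific: dual-luciferase
#' ratios with an internal Renilla control are comparatively precise
#' (sdlog 0.12), while densitometric western-blot and fractionation readouts
#' carry a higher coefficient of variation (sdlog 0.20).
#'
#' @param assay_variables assay variable names; transactivation variables are
#'   those matching `"^TA"`.
#' @param replicate_sd multiplicative replicate noise sdlog; NULL for the
#'   assay-specific defaults (0.12 for transactivation variables, 0.20 for
#'   the blot-based variables), or a scalar applied to all variables.
#' @param prevalences length-3 numeric summing to 1 (WT_LIKE, INTERMEDIATE,
#'   DAMAGING).
#' @return named list of three [class_profile()] objects.
#' @export
default_class_profiles <- function(assay_variables = DEFAULT_ASSAYS,
                                   replicate_sd = NULL,
                                   prevalences = c(0.4, 0.3, 0.3)) {
  stopifnot(length(prevalences) == 3L, abs(sum(prevalences) - 1) < 1e-9)
  ta <- grepl("^TA", assay_variables)
  if (is.null(replicate_sd)) {
    replicate_sd <- stats::setNames(ifelse(ta, 0.12, 0.20), assay_variables)
  }
  mk <- function(ta_mean, other_mean) {
    stats::setNames(ifelse(ta, ta_mean, other_mean), assay_variables)
  }
  list(
    WT_LIKE = class_profile("WT_LIKE", mk(1.0, 1.0), replicate_sd, prevalences[1]),
    INTERMEDIATE = class_profile("INTERMEDIATE", mk(0.6, 0.8), replicate_sd,
                                 prevalences[2]),
    DAMAGING = class_profile("DAMAGING", mk(0.3, 0.5), replicate_sd,
                             prevalences[3])
  )
}

#' Panel specification for the synthetic generator
#'
#' @param n_variants_per_lab exome-detected variants measured per laboratory.
#' @param n_replicates biological replicates per (variant, assay).
#' @param labs laboratory identifiers.
#' @param shared_variant_count exome-detected variants measured by every
#'   laboratory (benchmark subset); must be <= `n_variants_per_lab`.
#' @param lab_effect_sd sdlog of the multiplicative per-(lab, assay) batch
#'   factor.
#' @param assay_variables ordered assay variable names.
#' @param seed integer root seed; expanded into independent substreams for
#'   the panel, the references and the registry.
#' @return an object of class `panel_spec`.
#' @export
panel_spec <- function(n_variants_per_lab = 40L, n_replicates = 3L,
                       labs = c("Oxford", "Bergen"),
                       shared_variant_count = 5L, lab_effect_sd = 0.15,
                       assay_variables = DEFAULT_ASSAYS, seed = 1L) {
  if (n_variants_per_lab < 1L || n_replicates < 1L) {
    stop("counts must be positive")
  }
  if (shared_variant_count > n_variants_per_lab) {
    stop("shared_variant_count must be <= n_variants_per_lab")
  }
  if (shared_variant_count < 0L) stop("counts must be positive")
  if (!length(assay_variables)) stop("assay_variables must be non-empty")
  stopifnot(lab_effect_sd >= 0, length(labs) >= 1L)
  structure(list(n_variants_per_lab = as.integer(n_variants_per_lab),
                 n_replicates = as.integer(n_replicates),
                 labs = as.character(labs),
                 shared_variant_count = as.integer(shared_variant_count),
                 lab_effect_sd = lab_effect_sd,
                 assay_variables = as.character(assay_variables),
                 seed = as.integer(seed)),
            class = "panel_spec")
}

# Per-(lab, assay) batch factors; deterministic in the root seed alone so the
# panel and the reference battery experience the same batch effect.
lab_factors <- function(spec) {
  s <- derive_seeds(spec$seed, "lab_effect")
  with_seed(s[["lab_effect"]], {
    m <- matrix(exp(stats::rnorm(length(spec$labs) * length(spec$assay_variables),
                                 0, spec$lab_effect_sd)),
                nrow = length(spec$labs),
                dimnames = list(spec$labs, spec$assay_variables))
    m
  })
}

# Mean-one multiplicative log-normal replicate noise.
replicate_noise <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sdlog) - sdlog^2 / 2)
}

# Class-conditional placement over the positional bands that drive the
# isoform/domain scores: DNA-binding/dimerization region (1-287), early
# transactivation domain (288-414, still in the all-isoform exons),
# exon 7 (415-487), and the hepatocyte-dominant exons 8-10 (488-631).
# Damaging variants concentrate in the mutation-intolerant DNA-binding
# region; intermediate (T2D-risk) and wild-type-like variants are
# tolerated especially in the late, liver-dominant exons.
RESIDUE_BANDS <- cbind(start = c(1L, 288L, 415L, 488L),
                       end = c(287L, 414L, 487L, 631L))
BAND_PROBS <- rbind(WT_LIKE = c(0.02, 0.01, 0.27, 0.70),
                    INTERMEDIATE = c(0.03, 0.02, 0.25, 0.70),
                    DAMAGING = c(0.90, 0.07, 0.02, 0.01))

class_conditional_residues <- function(classes) {
  n <- length(classes)
  res <- integer(n)
  for (i in seq_len(n)) {
    b <- sample.int(4L, 1L, prob = BAND_PROBS[classes[i], ])
    res[i] <- sample(RESIDUE_BANDS[b, "start"]:RESIDUE_BANDS[b, "end"], 1L)
  }
  res
}

random_variant_names <- function(classes, taken = character()) {
  n <- length(classes)
  res <- integer(n)
  nm <- character(n)
  todo <- seq_len(n)
  while (length(todo)) {
    res[todo] <- class_conditional_residues(classes[todo])
    ref <- sample(AA3, length(todo), replace = TRUE)
    alt <- sample(AA3, length(todo), replace = TRUE)
    nm[todo] <- paste0("p.", ref, res[todo], alt)
    bad <- rep(FALSE, n)
    bad[todo] <- ref == alt
    bad <- bad | duplicated(nm) | nm %in% taken
    todo <- which(bad)
  }
  data.frame(variant = nm, residue = res, stringsAsFactors = FALSE)
}

measure_block <- function(variants, classes, lab, spec, profiles, lf) {
  rows <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    prof <- profiles[[classes[i]]]
    blocks <- lapply(spec$assay_variables, function(a) {
      mu <- prof$mean_activity[[a]] * lf[lab, a]
      data.frame(variant = variants[i], lab = lab, assay = a,
                 replicate = seq_len(spec$n_replicates),
                 value = mu * replicate_noise(spec$n_replicates,
                                              prof$replicate_sd[[a]]),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, blocks)
  }
  do.call(rbind, rows)
}

#' Generate a two-laboratory functional assay panel
#'
#' Draws latent classes by profile prevalence, assigns each laboratory its
#' own exome-detected variants plus the shared benchmark subset, and emits
#' replicate-level control-normalized measurements. The expected value of a
#' measurement is the variant's class mean times the per-(lab, assay)
#' log-normal batch factor; replicate noise is mean-one log-normal. Truth
#' labels are returned separately and never written into the dataset payload.
#'
#' @param spec a [panel_spec()].
#' @param profiles named list of [class_profile()] objects covering all three
#'   classes.
#' @return list with elements `dataset` ([functional_dataset()]),
#'   `annotations` ([variant_annotation()]) and `truth` (data.frame
#'   `variant`, `class_label`).
#' @export
generate_panel <- function(spec, profiles = default_class_profiles(spec$assay_variables)) {
  stopifnot(inherits(spec, "panel_spec"))
  stopifnot(all(CLASS_LABELS %in% names(profiles)))
  for (p in profiles) {
    stopifnot(inherits(p, "class_profile"),
              setequal(names(p$mean_activity), spec$assay_variables))
  }
  prev <- vapply(profiles[CLASS_LABELS], function(p) p$prevalence, 0)
  if (abs(sum(prev) - 1) > 1e-9) stop("class prevalences must sum to 1")
  lf <- lab_factors(spec)
  seeds <- derive_seeds(spec$seed, "panel")

  with_seed(seeds[["panel"]], {
    n_unique <- length(spec$labs) * (spec$n_variants_per_lab -
                                       spec$shared_variant_count) +
      spec$shared_variant_count
    classes <- sample(CLASS_LABELS, n_unique, replace = TRUE, prob = prev)
    named <- random_variant_names(classes,
                                  taken = reference_roster()$variant)
    variants <- named$variant
    shared <- variants[seq_len(spec$shared_variant_count)]
    rest <- if (spec$shared_variant_count > 0L) {
      variants[-seq_len(spec$shared_variant_count)]
    } else variants
    per_lab <- spec$n_variants_per_lab - spec$shared_variant_count
    own <- split(rest, rep(spec$labs, each = per_lab))

    names(classes) <- variants
    blocks <- lapply(spec$labs, function(lab) {
      v <- c(shared, own[[lab]])
      measure_block(v, classes[v], lab, spec, profiles, lf)
    })
    ds <- functional_dataset(do.call(rbind, blocks), "CONTROL_NORMALIZED")

    parsed <- named
    origin <- rep(NA_character_, n_unique)
    origin[match(shared, variants)] <- "shared"
    for (lab in spec$labs) origin[match(own[[lab]], variants)] <- lab
    ann <- variant_annotation(data.frame(
      variant = variants,
      residue = parsed$residue,
      exon = residue_to_exon(parsed$residue),
      gnomad_count = NA_integer_,
      reference_role = "NONE",
      lab = origin,
      stringsAsFactors = FALSE
    ))
    truth <- data.frame(variant = variants, class_label = unname(classes),
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$variant), , drop = FALSE]
    rownames(truth) <- NULL
    list(dataset = ds, annotations = ann, truth = truth)
  })
}

# Reference battery shared by both laboratories: two wild-type backgrounds,
# six MODY-positive controls (damaging profile), two type 2 diabetes risk
# controls (intermediate profile). The wild-type constructs (Ile27 and
# Leu27 backgrounds) carry no mutated residue, so their position scores
# are pinned to the most tolerant band (liver-dominant exon /
# transactivation domain) via a nominal residue of 600.
reference_roster <- function() {
  data.frame(
    variant = c("WT_Ile27", "WT_Leu27",
                "p.Pro112Leu", "p.Arg203His", "p.Ala116Val", "p.Arg159Trp",
                "p.Arg271Trp", "p.Pro379Thr",
                "p.Glu508Lys", "p.Ser487Asn"),
    residue = c(600L, 600L, 112L, 203L, 116L, 159L, 271L, 379L, 508L, 487L),
    reference_role = c("WILD_TYPE", "WILD_TYPE",
                       rep("MODY_REFERENCE", 6L),
                       rep("T2D_REFERENCE", 2L)),
    class_label = c("WT_LIKE", "WT_LIKE", rep("DAMAGING", 6L),
                    rep("INTERMEDIATE", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Generate the shared reference-variant battery
#'
#' Every laboratory measures the same reference battery: the two wild-type
#' backgrounds (Ile27 and Leu27), six MODY-positive controls drawn from the
#' DAMAGING profile, and two type 2 diabetes risk controls drawn from the
#' INTERMEDIATE profile. Reference roles are flagged in the annotations.
#'
#' @inheritParams generate_panel
#' @return list with elements `dataset`, `annotations`, `truth` as in
#'   [generate_panel()].
#' @export
generate_references <- function(spec, profiles = default_class_profiles(spec$assay_variables)) {
  stopifnot(inherits(spec, "panel_spec"))
  roster <- reference_roster()
  lf <- lab_factors(spec)
  seeds <- derive_seeds(spec$seed, "references")
  with_seed(seeds[["references"]], {
    blocks <- lapply(spec$labs, function(lab) {
      measure_block(roster$variant, roster$class_label, lab, spec, profiles, lf)
    })
    ds <- functional_dataset(do.call(rbind, blocks), "CONTROL_NORMALIZED")
    ann <- variant_annotation(data.frame(
      variant = roster$variant,
      residue = roster$residue,
      exon = residue_to_exon(roster$residue),
      gnomad_count = NA_integer_,
      reference_role = roster$reference_role,
      lab = "shared",
      stringsAsFactors = FALSE
    ))
    truth <- roster[order(roster$variant), c("variant", "class_label")]
    rownames(truth) <- NULL
    list(dataset = ds, annotations = ann, truth = truth)
  })
}

#' Generate a synthetic diagnostic-registry table
#'
#' Assigns 5-tier original classes correlated with the latent truth class
#' (WT_LIKE -> 1/2, INTERMEDIATE -> 3, DAMAGING -> 4/5) with a configurable
#' misclassification rate (one-tier shifts), and class-conditional gnomAD
#' allele counts: damaging variants are ultra-rare (count <= 2 by default),
#' intermediate variants fall in the low-frequency type 2 diabetes band
#' (3..121), wild-type-like variants above it.
#'
#' @param truth data.frame `variant`, `class_label` as returned by
#'   [generate_panel()].
#' @param seed integer seed.
#' @param misclassification_rate probability that a variant's registry class
#'   is shifted one tier away from its truth-implied class.
#' @param co_occurrence_rate probability of the co-occurring-pathogenic flag.
#' @param registry_id registry identifier.
#' @return a [registry_table()].
#' @export
generate_registry <- function(truth, seed = 1L, misclassification_rate = 0.1,
                              co_occurrence_rate = 0.05,
                              registry_id = "SYNTH") {
  stopifnot(is.data.frame(truth), all(c("variant", "class_label") %in% names(truth)))
  if (any(is.na(truth$class_label))) stop("labels must be present for all variants")
  seeds <- derive_seeds(seed, "registry")
  with_seed(seeds[["registry"]], {
    n <- nrow(truth)
    base <- integer(n)
    for (i in seq_len(n)) {
      base[i] <- switch(truth$class_label[i],
                        WT_LIKE = sample(1:2, 1L),
                        INTERMEDIATE = 3L,
                        DAMAGING = sample(4:5, 1L),
                        stop("unknown class label: ", truth$class_label[i]))
    }
    shift <- stats::rbinom(n, 1L, misclassification_rate) *
      sample(c(-1L, 1L), n, replace = TRUE)
    cls <- pmin(5L, pmax(1L, base + shift))
    count <- integer(n)
    for (i in seq_len(n)) {
      count[i] <- switch(truth$class_label[i],
                         WT_LIKE = sample(122:5000, 1L),
                         INTERMEDIATE = sample(3:121, 1L),
                         DAMAGING = sample(0:2, 1L))
    }
    registry_table(data.frame(
      variant = truth$variant,
      original_class = cls,
      registry_id = registry_id,
      co_occurring_pathogenic = stats::runif(n) < co_occurrence_rate,
      gnomad_count = count,
      stringsAsFactors = FALSE
    ))
  })
}
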