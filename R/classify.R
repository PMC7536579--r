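# Cluster zone annotation along the benign -> T2D-risk -> MODY continuum,
# allele-frequency bands, the reclassification rule engine, and the
# registry-level impact summary.

ZONES <- c("BENIGN", "INTERMEDIATE_T2D_RISK", "DAMAGING_MODY", "MIXED",
           "UNANNOTATED")
BANDS <- c("MODY_COMPATIBLE", "LOW_FREQ_T2D", "ABOVE_LOW_FREQ")

#' Annotate clusters with continuum zones from reference membership
#'
#' A cluster whose reference variants are exclusively wild-type is BENIGN;
#' exclusively type 2 diabetes risk controls, INTERMEDIATE_T2D_RISK;
#' exclusively MODY controls, DAMAGING_MODY. Clusters containing
#' conflicting reference roles are MIXED and are never silently resolved.
#' Reference-free clusters inherit the zone of the nearest annotated
#' cluster by centroid distance (flagged `inherited`) when coordinates are
#' supplied, and stay UNANNOTATED otherwise.
#'
#' @param assignment named integer vector (variant -> cluster id).
#' @param references data.frame with columns `variant`, `reference_role`.
#' @param points optional coordinate matrix (rownames = variants) used to
#'   compute centroids for zone inheritance.
#' @return an object of class `zone_map`: data.frame `cluster`, `zone`,
#'   `inherited`, `roster` (comma-joined reference variants).
#' @export
annotate_zones <- function(assignment, references, points = NULL) {
  stopifnot(!is.null(names(assignment)))
  refs <- references[references$reference_role != "NONE", , drop = FALSE]
  refs <- refs[refs$variant %in% names(assignment), , drop = FALSE]
  if (!nrow(refs)) stop("no reference variants present in the assignment")
  clusters <- sort(unique(assignment))
  zone <- character(length(clusters))
  roster <- character(length(clusters))
  for (i in seq_along(clusters)) {
    members <- names(assignment)[assignment == clusters[i]]
    rr <- refs[refs$variant %in% members, , drop = FALSE]
    roster[i] <- paste(rr$variant, collapse = ",")
    roles <- unique(rr$reference_role)
    zone[i] <- if (!length(roles)) "UNANNOTATED"
    else if (length(roles) > 1L) "MIXED"
    else switch(roles,
                WILD_TYPE = "BENIGN",
                T2D_REFERENCE = "INTERMEDIATE_T2D_RISK",
                MODY_REFERENCE = "DAMAGING_MODY")
  }
  inherited <- rep(FALSE, length(clusters))
  if (!is.null(points) && any(zone == "UNANNOTATED") &&
      any(!(zone %in% c("UNANNOTATED", "MIXED")))) {
    X <- as.matrix(points)
    cent <- t(vapply(clusters, function(cl) {
      colMeans(X[names(assignment)[assignment == cl], , drop = FALSE])
    }, numeric(ncol(X))))
    annotated <- which(!(zone %in% c("UNANNOTATED", "MIXED")))
    for (i in which(zone == "UNANNOTATED")) {
      d <- sqrt(rowSums(sweep(cent[annotated, , drop = FALSE], 2L,
                              cent[i, ])^2))
      zone[i] <- zone[annotated[which.min(d)]]
      inherited[i] <- TRUE
    }
  }
  structure(data.frame(cluster = clusters, zone = zone,
                       inherited = inherited, roster = roster,
                       stringsAsFactors = FALSE),
            class = c("zone_map", "data.frame"))
}

#' Zone of each variant under a zone map
#' @param assignment named cluster assignment.
#' @param zones a `zone_map`.
#' @return named character vector of zones.
#' @export
variant_zones <- function(assignment, zones) {
  stats::setNames(zones$zone[match(assignment, zones$cluster)],
                  names(assignment))
}

#' Allele-frequency band from gnomAD allele counts
#'
#' Bands partition the non-negative integers: counts <= `mody_max_count`
#' (default 2, AF < 0.0008%) are compatible with ultra-rare MODY-causing
#' alleles; counts up to `t2d_max_count` (default 121, AF < 0.04%) match
#' low-frequency type 2 diabetes predisposing alleles; anything above is
#' too frequent for either. Both thresholds are inclusive. When a count is
#' missing, an allele fraction (`af`, on [0,1]) may be supplied instead and
#' is banded with the corresponding AF cutoffs.
#'
#' @param allele_count non-negative integer vector (NA allowed if `af`
#'   given).
#' @param mody_max_count,t2d_max_count inclusive band thresholds.
#' @param af optional allele fractions used where `allele_count` is NA.
#' @param mody_max_af,t2d_max_af AF cutoffs (defaults 0.0008% and 0.04%).
#' @return character vector of bands.
#' @export
frequency_band <- function(allele_count, mody_max_count = 2L,
                           t2d_max_count = 121L, af = NULL,
                           mody_max_af = 8e-6, t2d_max_af = 4e-4) {
  if (any(allele_count < 0L, na.rm = TRUE)) {
    stop("allele counts must be non-negative")
  }
  band <- ifelse(allele_count <= mody_max_count, "MODY_COMPATIBLE",
                 ifelse(allele_count <= t2d_max_count, "LOW_FREQ_T2D",
                        "ABOVE_LOW_FREQ"))
  if (!is.null(af)) {
    use_af <- is.na(allele_count) & !is.na(af)
    band[use_af] <- ifelse(af[use_af] < mody_max_af, "MODY_COMPATIBLE",
                           ifelse(af[use_af] < t2d_max_af, "LOW_FREQ_T2D",
                                  "ABOVE_LOW_FREQ"))
  }
  band
}

#' Default reclassification rules
#'
#' An ordered, first-match rule list formalizing the registry re-evaluation
#' logic (each rule overridable or replaceable). With `v` the variant's
#' attributes (`original_class`, `zone`, `band`, `exon`,
#' `co_occurring_pathogenic`):
#'
#' * `R1` benign-evidence downgrade: original class 4/5, benign or
#'   intermediate zone, allele count above the MODY-compatible band ->
#'   propose class 3 (VUS/likely benign).
#' * `R2` liver-isoform downgrade: original class 4/5, damaging zone but
#'   hepatocyte-dominant exon band (8-10) and count above the
#'   MODY-compatible band -> propose class 3.
#' * `R3` co-occurrence downgrade: a co-occurring pathogenic variant with
#'   original class 4/5 -> propose class 3.
#' * `R4` VUS demotion: original class 3 with benign/intermediate-zone
#'   clustering, or damaging-zone clustering in the liver band, and count
#'   above the MODY-compatible band -> propose class 2 (likely benign).
#' * `R5` pathogenic support: damaging zone, beta-cell-relevant exons
#'   (<= 7) and MODY-compatible frequency -> retain (classification
#'   supported).
#' * otherwise -> retain.
#'
#' @return list of rules; each rule is a list with `id`, `description`,
#'   `when` (predicate on `v`) and `proposed_class` (function of the
#'   original class, or NULL to retain).
#' @export
default_rules <- function() {
  list(
    list(id = "R1",
         description = "class 4/5 in benign/intermediate zone, frequency above MODY band -> VUS/likely benign",
         when = function(v) v$original_class %in% 4:5 &&
           v$zone %in% c("BENIGN", "INTERMEDIATE_T2D_RISK") &&
           v$band != "MODY_COMPATIBLE",
         proposed_class = function(orig) 3L),
    list(id = "R2",
         description = "class 4/5 damaging zone but liver-dominant exon band and frequency above MODY band -> VUS/likely benign",
         when = function(v) v$original_class %in% 4:5 &&
           v$zone == "DAMAGING_MODY" && v$exon %in% 8:10 &&
           v$band != "MODY_COMPATIBLE",
         proposed_class = function(orig) 3L),
    list(id = "R3",
         description = "co-occurring pathogenic variant with class 4/5 -> VUS/likely benign",
         when = function(v) isTRUE(v$co_occurring_pathogenic) &&
           v$original_class %in% 4:5,
         proposed_class = function(orig) 3L),
    list(id = "R4",
         description = "class 3 in benign/intermediate zone or liver-band damaging zone, frequency above MODY band -> likely benign",
         when = function(v) v$original_class == 3L &&
           v$band != "MODY_COMPATIBLE" &&
           (v$zone %in% c("BENIGN", "INTERMEDIATE_T2D_RISK") ||
              (v$zone == "DAMAGING_MODY" && v$exon %in% 8:10)),
         proposed_class = function(orig) 2L),
    list(id = "R5",
         description = "damaging zone, exon <= 7, MODY-compatible frequency -> retain (supported)",
         when = function(v) v$zone == "DAMAGING_MODY" && v$exon <= 7L &&
           v$band == "MODY_COMPATIBLE",
         proposed_class = NULL)
  )
}

#' Apply the reclassification rule engine
#'
#' Evaluates the ordered rules on each variant; the first matching rule
#' fires. Variants in MIXED or UNANNOTATED zones, or with missing
#' attributes, are never guessed at: they abstain with status `UNREVIEWED`.
#' The evidence trace lists every rule evaluated and which one fired. The
#' engine is a pure function of its declared inputs.
#'
#' @param variants data.frame with columns `variant`, `original_class`,
#'   `zone`, `band`, `exon`; optionally `co_occurring_pathogenic` (default
#'   FALSE).
#' @param rules ordered rule list (see [default_rules()]).
#' @return data.frame `variant`, `original_class`, `proposed_class`,
#'   `changed`, `fired_rule`, `status`
#'   (REVIEWED/RETAINED/SUPPORTED/UNREVIEWED), `trace`.
#' @export
reclassify <- function(variants, rules = default_rules()) {
  stopifnot(is.data.frame(variants),
            all(c("variant", "original_class", "zone", "band", "exon") %in%
                  names(variants)))
  if (is.null(variants$co_occurring_pathogenic)) {
    variants$co_occurring_pathogenic <- FALSE
  }
  n <- nrow(variants)
  proposed <- integer(n)
  fired <- character(n)
  status <- character(n)
  trace <- character(n)
  for (i in seq_len(n)) {
    v <- as.list(variants[i, ])
    unresolved <- is.na(v$original_class) || is.na(v$zone) || is.na(v$band) ||
      is.na(v$exon) || v$zone %in% c("MIXED", "UNANNOTATED")
    if (unresolved) {
      proposed[i] <- NA_integer_
      fired[i] <- NA_character_
      status[i] <- "UNREVIEWED"
      trace[i] <- "unresolved zone/band/attributes: abstain"
      next
    }
    hit <- NA_integer_
    steps <- character(length(rules))
    for (j in seq_along(rules)) {
      ok <- isTRUE(rules[[j]]$when(v))
      steps[j] <- paste0(rules[[j]]$id, "=", ok)
      if (ok && is.na(hit)) hit <- j
    }
    trace[i] <- paste(steps, collapse = "; ")
    if (is.na(hit)) {
      proposed[i] <- v$original_class
      fired[i] <- "default"
      status[i] <- "RETAINED"
    } else {
      rule <- rules[[hit]]
      fired[i] <- rule$id
      if (is.null(rule$proposed_class)) {
        proposed[i] <- v$original_class
        status[i] <- "SUPPORTED"
      } else {
        proposed[i] <- rule$proposed_class(v$original_class)
        status[i] <- "REVIEWED"
      }
    }
  }
  data.frame(variant = variants$variant,
             original_class = variants$original_class,
             proposed_class = proposed,
             changed = !is.na(proposed) & proposed != variants$original_class,
             fired_rule = fired, status = status, trace = trace,
             stringsAsFactors = FALSE)
}

#' Registry-level reclassification impact
#'
#' @param proposals a [reclassify()] result covering the overlap set
#'   (variants shared between the functional panel and the registry).
#' @param n_registry_total total number of HNF1A missense variants in the
#'   registry (must be >= the overlap size).
#' @param registry_id label for printing.
#' @return an object of class `reclass_report`: `n_registry`, `n_overlap`,
#'   `n_reclassified`, `pct_of_registry`, `pct_of_overlap` (raw), and
#'   `pct_of_registry_rounded`, `pct_of_overlap_rounded` (nearest integer),
#'   plus the per-variant `proposals`.
#' @export
registry_report <- function(proposals, n_registry_total,
                            registry_id = "registry") {
  stopifnot(is.data.frame(proposals),
            all(c("original_class", "proposed_class", "changed") %in%
                  names(proposals)))
  n_overlap <- nrow(proposals)
  if (n_registry_total < n_overlap) {
    stop("n_registry_total (", n_registry_total,
         ") is smaller than the overlap (", n_overlap, ")")
  }
  n_re <- sum(proposals$changed, na.rm = TRUE)
  structure(list(registry_id = registry_id,
                 n_registry = as.integer(n_registry_total),
                 n_overlap = as.integer(n_overlap),
                 n_reclassified = as.integer(n_re),
                 pct_of_registry = 100 * n_re / n_registry_total,
                 pct_of_overlap = 100 * n_re / n_overlap,
                 pct_of_registry_rounded = round(100 * n_re / n_registry_total),
                 pct_of_overlap_rounded = round(100 * n_re / n_overlap),
                 proposals = proposals),
            class = "reclass_report")
}

#' @export
print.reclass_report <- function(x, ...) {
  cat("Reclassification impact (", x$registry_id, "):\n", sep = "")
  cat(sprintf("  %d of %d overlapping variants changed class (%.1f%% ~ %d%% of overlap)\n",
              x$n_reclassified, x$n_overlap, x$pct_of_overlap,
              x$pct_of_overlap_rounded))
  cat(sprintf("  %.1f%% ~ %d%% of the %d registry variants\n",
              x$pct_of_registry, x$pct_of_registry_rounded, x$n_registry))
  invisible(x)
}
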