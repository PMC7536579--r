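# Dataset polishing: EMSA exclusion, replicate aggregation, isoform/domain
# position scores, column standardization. Only internal-control-normalized
# data are accepted for clustering; raw and wild-type-normalized formats are
# inspectable through the io layer but rejected here.

DNA_BINDING_MAX_RESIDUE <- 287L
EMSA_PATTERN <- "(?i)emsa|dna[._ ]?bind"

#' Default isoform and domain score maps
#'
#' Ordinal position weights attached to each variant before clustering.
#' The isoform score follows the exon band: exons 1-6 are present in all
#' HNF1A isoforms (weight 3), exon 7 in two isoforms (weight 2), and exons
#' 8-10 only in the hepatocyte-dominant isoform (weight 1), reflecting the
#' diminishing beta-cell relevance of the latter exons. The domain score
#' weights the mutation-intolerant DNA-binding/dimerization region (residues
#' 1-287, weight 2) above the more tolerant transactivation domain
#' (weight 1). Both maps are fully overridable.
#'
#' @param all_isoforms,two_isoforms,liver_dominant isoform-band weights.
#' @param dna_binding,transactivation domain-band weights.
#' @return a named list used by [assign_position_scores()].
#' @export
default_position_scores <- function(all_isoforms = 3, two_isoforms = 2,
                                    liver_dominant = 1, dna_binding = 2,
                                    transactivation = 1) {
  list(isoform = c(ALL_ISOFORMS = all_isoforms, TWO_ISOFORMS = two_isoforms,
                   LIVER_DOMINANT = liver_dominant),
       domain = c(DNA_BINDING = dna_binding,
                  TRANSACTIVATION = transactivation))
}

#' Assign isoform and domain position scores
#'
#' @param annotations a [variant_annotation()] table (columns `exon` and
#'   `residue` are used).
#' @param score_map list as returned by [default_position_scores()].
#' @return data.frame `variant`, `isoform_band`, `domain_band`,
#'   `isoform_score`, `domain_score`.
#' @export
assign_position_scores <- function(annotations, score_map = default_position_scores()) {
  stopifnot(is.data.frame(annotations),
            all(c("variant", "exon", "residue") %in% names(annotations)))
  exon <- annotations$exon
  if (any(is.na(exon)) || any(!(exon %in% 1:10))) {
    stop("exon must be present and in 1..10 for all variants")
  }
  if (any(is.na(annotations$residue))) stop("residue must be present")
  iso_band <- ifelse(exon <= 6L, "ALL_ISOFORMS",
                     ifelse(exon == 7L, "TWO_ISOFORMS", "LIVER_DOMINANT"))
  dom_band <- ifelse(annotations$residue <= DNA_BINDING_MAX_RESIDUE,
                     "DNA_BINDING", "TRANSACTIVATION")
  data.frame(variant = annotations$variant,
             isoform_band = iso_band,
             domain_band = dom_band,
             isoform_score = unname(score_map$isoform[iso_band]),
             domain_score = unname(score_map$domain[dom_band]),
             stringsAsFactors = FALSE)
}

#' Drop EMSA / DNA-binding assay variables
#'
#' DNA binding was interrogated for only a subset of variants, so EMSA
#' variables never enter the multivariate analysis. A no-op when no EMSA
#' variable is present.
#'
#' @param ds a [functional_dataset()].
#' @param pattern regular expression identifying EMSA assay variables.
#' @return the dataset without EMSA rows.
#' @export
drop_emsa <- function(ds, pattern = EMSA_PATTERN) {
  stopifnot(inherits(ds, "functional_dataset"))
  keep <- !grepl(pattern, ds$assay, perl = TRUE)
  functional_dataset(as.data.frame(ds)[keep, , drop = FALSE], format_level(ds))
}

#' Variants warranting EMSA follow-up
#'
#' Selects variants located in the DNA-binding domain (residues 1-287) or
#' with any transactivation activity below 50% of wild-type. This mirrors
#' the wet-lab inclusion filter for DNA-binding assays; the selection is for
#' reporting only and EMSA data never enter clustering.
#'
#' @param annotations a [variant_annotation()] table.
#' @param ta_values data.frame with a `variant` column and one column per
#'   transactivation variable, values as fraction of wild-type.
#' @param ta_threshold activity threshold (fraction of wild-type).
#' @return data.frame `variant`, `in_dna_binding_domain`, `low_ta`,
#'   `ta_missing`, `selected`. Variants with missing transactivation values
#'   are flagged (`ta_missing`), not dropped.
#' @export
emsa_candidates <- function(annotations, ta_values, ta_threshold = 0.5) {
  stopifnot(is.data.frame(ta_values), "variant" %in% names(ta_values))
  idx <- match(annotations$variant, ta_values$variant)
  ta <- as.matrix(ta_values[idx, setdiff(names(ta_values), "variant"),
                            drop = FALSE])
  in_domain <- annotations$residue <= DNA_BINDING_MAX_RESIDUE
  missing <- apply(ta, 1L, function(r) any(is.na(r)))
  low <- apply(ta, 1L, function(r) any(r < ta_threshold, na.rm = TRUE))
  data.frame(variant = annotations$variant,
             in_dna_binding_domain = in_domain,
             low_ta = low,
             ta_missing = missing,
             selected = in_domain | low,
             stringsAsFactors = FALSE)
}

#' Aggregate replicates to one value per variant and assay variable
#'
#' @param ds a [functional_dataset()] at `CONTROL_NORMALIZED` level.
#' @param method `"mean"` (default) or `"median"`.
#' @return numeric matrix (variants x assay variables, rows sorted by
#'   variant key) with attributes `n_replicates` (matrix of per-cell
#'   replicate counts) and `replicate_sd` (per-cell SDs, metadata only).
#' @export
aggregate_replicates <- function(ds, method = c("mean", "median")) {
  stopifnot(inherits(ds, "functional_dataset"))
  method <- match.arg(method)
  if (format_level(ds) != "CONTROL_NORMALIZED") {
    stop("replicate aggregation expects CONTROL_NORMALIZED data, got ",
         format_level(ds))
  }
  if (length(unique(ds$lab)) > 1L) {
    stop("dataset contains ", length(unique(ds$lab)),
         " labs; analyze each laboratory separately (subset by lab first)")
  }
  fun <- if (method == "mean") mean else stats::median
  variants <- sort(unique(ds$variant))
  assays <- unique(ds$assay)
  agg <- function(f) {
    m <- tapply(ds$value, list(ds$variant, ds$assay), f)
    m[variants, assays, drop = FALSE]
  }
  values <- agg(fun)
  counts <- agg(length)
  counts[is.na(counts)] <- 0L
  if (any(counts == 0L)) {
    offenders <- which(counts == 0L, arr.ind = TRUE)
    stop("no replicates for: ",
         paste(rownames(counts)[offenders[, 1L]],
               colnames(counts)[offenders[, 2L]], sep = "/", collapse = ", "))
  }
  sds <- agg(function(v) if (length(v) > 1L) stats::sd(v) else NA_real_)
  attr(values, "n_replicates") <- counts
  attr(values, "replicate_sd") <- sds
  values
}

#' Polishing configuration
#'
#' @param aggregate replicate aggregation method, `"mean"` or `"median"`.
#' @param score_map isoform/domain score maps
#'   ([default_position_scores()]).
#' @param emsa_pattern regular expression for EMSA variables.
#' @return a list of class `polish_config`.
#' @export
polish_config <- function(aggregate = "mean",
                          score_map = default_position_scores(),
                          emsa_pattern = EMSA_PATTERN) {
  structure(list(aggregate = aggregate, score_map = score_map,
                 emsa_pattern = emsa_pattern), class = "polish_config")
}

#' Polish a functional dataset for multivariate analysis
#'
#' Pipeline: drop EMSA variables, aggregate replicates, append the isoform
#' and domain position scores, then zero-center and scale every column to
#' unit sample variance (n-1 denominator). Constant columns are rejected by
#' name. Row order is deterministic (sorted by variant key).
#'
#' @param ds a [functional_dataset()] at `CONTROL_NORMALIZED` level
#'   (single laboratory).
#' @param annotations a [variant_annotation()] covering every variant in
#'   `ds`.
#' @param config a [polish_config()].
#' @return a `polished_matrix`: numeric matrix (variants x variables), each
#'   column mean 0 and sample SD 1, with attributes `center`, `scale`,
#'   `n_replicates`, `provenance`.
#' @export
polish_dataset <- function(ds, annotations, config = polish_config()) {
  stopifnot(inherits(ds, "functional_dataset"))
  if (format_level(ds) != "CONTROL_NORMALIZED") {
    stop("polishing requires CONTROL_NORMALIZED data, got ", format_level(ds))
  }
  ds <- drop_emsa(ds, config$emsa_pattern)
  values <- aggregate_replicates(ds, config$aggregate)
  variants <- rownames(values)
  missing_ann <- setdiff(variants, annotations$variant)
  if (length(missing_ann)) {
    stop("missing annotation for variant(s): ",
         paste(utils::head(missing_ann, 5L), collapse = ", "))
  }
  ann <- annotations[match(variants, annotations$variant), , drop = FALSE]
  scores <- assign_position_scores(ann, config$score_map)
  full <- cbind(values,
                isoform_score = scores$isoform_score,
                domain_score = scores$domain_score)
  sds <- apply(full, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s) cannot be standardized: ",
         paste(colnames(full)[sds == 0], collapse = ", "))
  }
  scaled <- scale(full, center = TRUE, scale = sds)
  out <- scaled[, , drop = FALSE]
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "center") <- attr(scaled, "scaled:center")
  attr(out, "scale") <- attr(scaled, "scaled:scale")
  attr(out, "n_replicates") <- attr(values, "n_replicates")
  attr(out, "provenance") <- list(
    format_level = "CONTROL_NORMALIZED",
    aggregate = config$aggregate,
    assay_variables = colnames(values),
    score_map = config$score_map,
    lab = unique(ds$lab)
  )
  class(out) <- c("polished_matrix", class(out))
  out
}

#' Write a polished matrix with a provenance sidecar
#'
#' @param x a `polished_matrix`.
#' @param path output TSV path; a JSON sidecar `<path>.json` records the
#'   polishing configuration and its hash.
#' @return `path`, invisibly.
#' @export
write_polished_matrix <- function(x, path) {
  stopifnot(inherits(x, "polished_matrix"))
  df <- data.frame(variant = rownames(x), as.data.frame(unclass(x)[, ]),
                   check.names = FALSE)
  write_tsv(df, path)
  prov <- attr(x, "provenance")
  prov$config_hash <- digest_config(prov)
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

digest_config <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(x)), tmp)
  unname(tools::md5sum(tmp))
}
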