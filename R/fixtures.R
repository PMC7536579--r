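# Curated registry-overlap fixtures.

#' Curated registry-overlap tables
#'
#' The 31-variant UK and 19-variant Norway overlap tables used for the
#' worked reclassification examples. Rows for the narratively documented
#' variants carry their reported attributes (cluster zone, exon band,
#' gnomAD allele count, co-occurrence); the remaining rows are constructed
#' to be consistent with their retained classifications and are flagged in
#' the `provenance` column (`constructed` / `count_constructed` /
#' `class_constructed`) — they are a partly synthetic stand-in, not source
#' data. The allele-frequency `band` column is computed on load with
#' [frequency_band()].
#'
#' @param registry `"UK"` or `"NORWAY"`.
#' @return data.frame with columns `variant`, `original_class`, `zone`,
#'   `exon`, `gnomad_count`, `co_occurring_pathogenic`, `provenance`,
#'   `band`.
#' @export
registry_fixture <- function(registry = c("UK", "NORWAY")) {
  registry <- match.arg(registry)
  fname <- switch(registry,
                  UK = "uk_overlap_curated_partly_synthetic.tsv",
                  NORWAY = "norway_overlap_curated_partly_synthetic.tsv")
  path <- system.file("extdata", fname, package = "hnf1astrat")
  if (path == "") stop("fixture file not found: ", fname)
  x <- read_tsv(path)
  x$band <- frequency_band(x$gnomad_count)
  x
}

#' Registry sizes for the two diagnostic registries
#'
#' Total numbers of documented HNF1A missense variants: 162 (UK) and 53
#' (Norway), used as denominators for registry-level impact percentages.
#'
#' @param registry `"UK"` or `"NORWAY"`.
#' @return integer scalar.
#' @export
registry_size <- function(registry = c("UK", "NORWAY")) {
  switch(match.arg(registry), UK = 162L, NORWAY = 53L)
}
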