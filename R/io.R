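# Data model and TSV readers/writers for functional datasets, variant
# annotations and registry tables. All tables are long/tidy, UTF-8, tab
# separated, "NA" for missing, with deterministic (key-sorted) row order on
# write so outputs are diffable.

FORMAT_LEVELS <- c("RAW", "CONTROL_NORMALIZED", "WT_NORMALIZED")
REFERENCE_ROLES <- c("NONE", "WILD_TYPE", "MODY_REFERENCE", "T2D_REFERENCE")

FUNCTIONAL_COLS <- c("variant", "lab", "assay", "replicate", "value")
ANNOTATION_COLS <- c("variant", "residue", "exon", "gnomad_count",
                     "reference_role", "lab")
REGISTRY_COLS <- c("variant", "original_class", "registry_id",
                   "co_occurring_pathogenic", "gnomad_count")

#' Construct a functional dataset
#'
#' A functional dataset holds internal-control-normalized assay measurements
#' in long format: one row per (variant, lab, assay, replicate). A single
#' normalization format level applies to the whole dataset; only
#' `CONTROL_NORMALIZED` data are accepted for clustering downstream.
#'
#' @param x data.frame with columns `variant`, `lab`, `assay`, `replicate`,
#'   `value`.
#' @param format_level one of `"RAW"`, `"CONTROL_NORMALIZED"`,
#'   `"WT_NORMALIZED"`.
#' @return an object of class `functional_dataset` (a data.frame).
#' @export
functional_dataset <- function(x, format_level = "CONTROL_NORMALIZED") {
  format_level <- match.arg(format_level, FORMAT_LEVELS)
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(FUNCTIONAL_COLS, names(x))
  if (length(missing_cols)) {
    stop("functional table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[FUNCTIONAL_COLS]
  x$variant <- as.character(x$variant)
  x$lab <- as.character(x$lab)
  x$assay <- as.character(x$assay)
  x$replicate <- as.integer(x$replicate)
  x$value <- as.numeric(x$value)
  if (nrow(x)) {
    if (any(!is.finite(x$value))) stop("non-finite measurement values")
    key <- paste(x$variant, x$lab, x$assay, x$replicate, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      stop("duplicate (variant, lab, assay, replicate) key(s): ",
           paste(gsub("\r", "/", utils::head(dup, 5L)), collapse = "; "))
    }
  }
  rownames(x) <- NULL
  structure(x, format_level = format_level,
            class = c("functional_dataset", "data.frame"))
}

#' @export
print.functional_dataset <- function(x, ...) {
  cat("Functional dataset:", length(unique(x$variant)), "variants,",
      length(unique(x$lab)), "lab(s),", length(unique(x$assay)),
      "assay variables,", nrow(x), "measurements\n")
  cat("Format level:", format_level(x), "\n")
  invisible(x)
}

#' Format level of a functional dataset
#' @param ds a `functional_dataset`.
#' @return character scalar.
#' @export
format_level <- function(ds) attr(ds, "format_level")

sort_functional <- function(ds) {
  ds[order(ds$variant, ds$lab, ds$assay, ds$replicate), , drop = FALSE]
}

#' Read a functional assay table from TSV
#'
#' @param path file path.
#' @param format_level declared normalization level of the file.
#' @return a [functional_dataset()].
#' @export
read_functional_table <- function(path, format_level = "CONTROL_NORMALIZED") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character", na.strings = "NA",
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(FUNCTIONAL_COLS, names(raw))
  if (length(missing_cols)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(val) & !is.na(raw$value))
  if (length(bad)) {
    stop("non-numeric value(s) in ", path, " at data line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  raw$value <- val
  rep_int <- suppressWarnings(as.integer(raw$replicate))
  bad <- which(is.na(rep_int) & !is.na(raw$replicate))
  if (length(bad)) {
    stop("non-integer replicate index in ", path, " at data line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  raw$replicate <- rep_int
  functional_dataset(raw, format_level = format_level)
}

#' Write a functional assay table as TSV
#'
#' Rows are sorted by (variant, lab, assay, replicate) so repeated writes of
#' the same dataset are byte-identical.
#'
#' @param ds a [functional_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_functional_table <- function(ds, path) {
  stopifnot(inherits(ds, "functional_dataset"))
  write_tsv(sort_functional(as.data.frame(ds)), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, na.strings = "NA", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Construct / validate a variant annotation table
#'
#' One row per variant: HGVS p. name (or an opaque label for non-missense
#' controls), residue, exon (1-10 on the canonical HNF1A gene model), gnomAD
#' allele count and reference role.
#'
#' @param x data.frame with columns `variant`, `residue`, `exon`,
#'   `gnomad_count`, `reference_role`, `lab`.
#' @return validated data.frame of class `variant_annotation`.
#' @export
variant_annotation <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(ANNOTATION_COLS, names(x))
  if (length(missing_cols)) {
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[ANNOTATION_COLS]
  x$variant <- as.character(x$variant)
  x$residue <- as.integer(x$residue)
  x$exon <- as.integer(x$exon)
  x$gnomad_count <- as.integer(x$gnomad_count)
  x$reference_role <- as.character(x$reference_role)
  x$lab <- as.character(x$lab)
  if (anyDuplicated(x$variant)) stop("duplicate variant annotation rows")
  if (any(x$residue < 1L, na.rm = TRUE)) stop("residue must be >= 1")
  if (any(!(x$exon %in% 1:10), na.rm = TRUE)) stop("exon must be in 1..10")
  if (any(x$gnomad_count < 0L, na.rm = TRUE)) stop("gnomad_count must be >= 0")
  if (any(!(x$reference_role %in% REFERENCE_ROLES))) {
    stop("reference_role must be one of: ",
         paste(REFERENCE_ROLES, collapse = ", "))
  }
  rownames(x) <- NULL
  structure(x[order(x$variant), , drop = FALSE],
            class = c("variant_annotation", "data.frame"))
}

#' Read / write variant annotation tables
#' @param path file path.
#' @rdname variant_annotation_io
#' @export
read_annotation_table <- function(path) variant_annotation(read_tsv(path))

#' @param x a `variant_annotation` table.
#' @rdname variant_annotation_io
#' @export
write_annotation_table <- function(x, path) {
  x <- variant_annotation(x)
  write_tsv(as.data.frame(x), path)
  invisible(path)
}

#' Construct / validate a registry table
#'
#' Original diagnostic-registry classifications on the 5-tier scale
#' (1 benign, 2 likely benign, 3 VUS, 4 likely pathogenic, 5 pathogenic),
#' with gnomAD allele counts and a flag for co-occurrence with another
#' pathogenic variant.
#'
#' @param x data.frame with columns `variant`, `original_class`,
#'   `registry_id`, `co_occurring_pathogenic`, `gnomad_count`.
#' @return validated data.frame of class `registry_table`.
#' @export
registry_table <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(REGISTRY_COLS, names(x))
  if (length(missing_cols)) {
    stop("registry table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[REGISTRY_COLS]
  x$variant <- as.character(x$variant)
  x$original_class <- as.integer(x$original_class)
  x$registry_id <- as.character(x$registry_id)
  x$co_occurring_pathogenic <- as.logical(x$co_occurring_pathogenic)
  x$gnomad_count <- as.integer(x$gnomad_count)
  if (any(!(x$original_class %in% 1:5))) stop("original_class must be in 1..5")
  if (anyDuplicated(x$variant)) stop("duplicate registry rows for a variant")
  rownames(x) <- NULL
  structure(x[order(x$variant), , drop = FALSE],
            class = c("registry_table", "data.frame"))
}

#' Read / write registry tables
#' @param path file path.
#' @rdname registry_table_io
#' @export
read_registry_table <- function(path) registry_table(read_tsv(path))

#' @param x a `registry_table`.
#' @rdname registry_table_io
#' @export
write_registry_table <- function(x, path) {
  x <- registry_table(x)
  write_tsv(as.data.frame(x), path)
  invisible(path)
}
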