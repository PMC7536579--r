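# HGVS protein-name parsing and the canonical HNF1A gene model.

#' Three-letter amino-acid codes
#'
#' The 20 standard amino acids, three-letter codes, as used in HGVS p. names.
#' @keywords internal
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

#' Parse HGVS protein-level missense names
#'
#' Parses names of the form `p.Glu508Lys` into reference amino acid, 1-based
#' residue position and alternate amino acid. Only simple missense
#' substitutions with three-letter codes are accepted; in-frame deletions and
#' other events (e.g. the `p.delB` nuclear-localization control) must be
#' carried as opaque labels instead.
#'
#' @param name character vector of HGVS p. names.
#' @return a data.frame with columns `hgvs_p`, `ref_aa`, `residue`, `alt_aa`,
#'   one row per input name.
#' @examples
#' parse_protein_hgvs(c("p.Glu508Lys", "p.Ile27Leu"))
#' @export
parse_protein_hgvs <- function(name) {
  stopifnot(is.character(name), length(name) >= 1L)
  m <- regmatches(name, regexec("^p\\.([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", name))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed HGVS protein name(s): ", paste(name[bad], collapse = ", "))
  }
  ref <- vapply(m, `[`, "", 2L)
  res <- as.integer(vapply(m, `[`, "", 3L))
  alt <- vapply(m, `[`, "", 4L)
  unknown <- !(ref %in% AA3) | !(alt %in% AA3)
  if (any(unknown)) {
    stop("unknown amino-acid code in: ", paste(name[unknown], collapse = ", "))
  }
  if (any(res < 1L)) stop("residue positions must be >= 1")
  data.frame(hgvs_p = name, ref_aa = ref, residue = res, alt_aa = alt,
             stringsAsFactors = FALSE)
}

#' Approximate exon boundaries of the canonical 10-exon HNF1A gene model
#'
#' Residue bands for the 631-amino-acid HNF1A protein (NM_000545 coding
#' model). The boundaries are approximate but respect the positions that
#' matter downstream: the DNA-binding/dimerization region (residues 1-287)
#' falls in exons 1-4, and the hepatocyte-dominant isoform band comprises
#' exons 8-10 (residues >= 488).
#'
#' @return data.frame with columns `exon`, `start`, `end` (residues,
#'   inclusive).
#' @export
hnf1a_exon_map <- function() {
  data.frame(
    exon  = 1:10,
    start = c(1, 43, 129, 203, 289, 360, 415, 488, 541, 589),
    end   = c(42, 128, 202, 288, 359, 414, 487, 540, 588, 631)
  )
}

#' Map residue positions to HNF1A exons
#'
#' @param residue integer vector of 1-based residue positions (1..631).
#' @param exon_map data.frame as returned by [hnf1a_exon_map()].
#' @return integer vector of exon numbers.
#' @export
residue_to_exon <- function(residue, exon_map = hnf1a_exon_map()) {
  stopifnot(is.numeric(residue), all(residue >= 1))
  if (any(residue > max(exon_map$end))) {
    stop("residue beyond the end of the protein (", max(exon_map$end), " aa)")
  }
  idx <- findInterval(residue, exon_map$start)
  exon_map$exon[idx]
}
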