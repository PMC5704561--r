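# Standard genetic code helpers built on Biostrings::GENETIC_CODE.

#' @noRd
genetic_code <- function() {
  if (is.null(.pkg_cache$GC)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$GC <- setNames(as.character(gc), names(gc))
  }
  .pkg_cache$GC
}

# The 61 sense codons, fixed order.
#' @noRd
sense_codons <- function() {
  if (is.null(.pkg_cache$SENSE)) {
    gc <- genetic_code()
    .pkg_cache$SENSE <- sort(names(gc)[gc != "*"])
  }
  .pkg_cache$SENSE
}

#' Translate in-frame coding sequences
#'
#' Translates CDS strings under the standard genetic code. Codons containing
#' the gap character translate to \code{"-"}.
#'
#' @param cds character vector of in-frame nucleotide sequences (lengths
#'   divisible by 3; may contain \code{-} in whole-codon gaps).
#' @return character vector of amino-acid sequences.
#' @export
translate_cds <- function(cds) {
  gc <- genetic_code()
  vapply(cds, function(s) {
    if (nchar(s) %% 3 != 0)
      stop("CDS length not divisible by 3: ", nchar(s))
    if (nchar(s) == 0) return("")
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- ifelse(grepl("-", cods, fixed = TRUE), "-", gc[cods])
    if (anyNA(aa))
      stop("unknown codon in CDS: ", cods[which(is.na(aa))[1]])
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
split_codons <- function(s) {
  n <- nchar(s)
  substring(s, seq(1, n, 3), seq(3, n, 3))
}
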