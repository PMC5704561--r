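# Shared internals: alphabets, scoring matrices, seeded substreams.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
NUC4 <- c("A","C","G","T")

#' @noRd
blosum62 <- function() {
  if (is.null(.pkg_cache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$B62 <- e$BLOSUM62[AA20, AA20]
  }
  .pkg_cache$B62
}

#' @noRd
nuc_matrix <- function(match = 1, mismatch = -1) {
  m <- matrix(mismatch, 4, 4, dimnames = list(NUC4, NUC4))
  diag(m) <- match
  m
}

# Gap costs: a length-k gap costs open + (k-1) * ext.
gap_costs <- function(kind) {
  if (kind == "protein") c(open = 11, ext = 1) else c(open = 5, ext = 2)
}

score_matrix_for <- function(kind) {
  if (kind == "protein") blosum62() else nuc_matrix()
}

# Deterministic substream seed from a master seed and a stage label, so that
# adding a pipeline stage never perturbs the random draws of earlier stages.
#' @noRd
derive_seed <- function(seed, label) {
  s <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(label)) s <- (s * 131 + k) %% 2147483629
  as.integer(s %% 2147483629 + 1)
}

# Evaluate code under a temporary RNG state seeded from (seed, label).
#' @noRd
with_stream <- function(seed, label, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, label))
  force(code)
}

#' @noRd
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# rows of gapped strings -> character matrix (rows x columns)
#' @noRd
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0) return(matrix(character(), 0, 0))
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

#' @noRd
collapse_rows <- function(mat) apply(mat, 1, paste, collapse = "")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
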