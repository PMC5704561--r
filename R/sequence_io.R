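# Readers/writers for FASTA, Newick and gene feature tables, with strict
# validation: malformed records are rejected, never silently repaired (the
# one documented exception is the annotation -> "other" mapping).

FEATURE_COLS <- c("genome_id", "contig_id", "gene_id", "start", "end",
                  "strand", "annotation", "replicon_class")

ANNOTATION_VOCAB <- c("cas1", "cas2", "cas4", "cas4/cas1 fusion", "cas6",
                      "crispr_array", "mge_marker", "other")

REPLICON_CLASSES <- c("chromosome", "plasmid", "viral", "unknown")

#' Construct a set of sequence records
#'
#' The package's basic sequence container: a data frame with columns
#' \code{id}, \code{genome_id}, \code{residues}, \code{kind}. Each record is
#' self-describing: the genome of origin travels with the sequence.
#'
#' @param id unique record identifiers.
#' @param genome_id genome of origin per record.
#' @param residues residue strings (upper case).
#' @param kind one of \code{"protein"}, \code{"cds"}, \code{"rrna"}.
#' @return a data frame of class \code{seq_records}.
#' @export
sequence_records <- function(id, genome_id, residues, kind) {
  kind <- match.arg(kind, c("protein", "cds", "rrna"))
  id <- as.character(id); genome_id <- as.character(genome_id)
  residues <- toupper(as.character(residues))
  if (anyDuplicated(id))
    stop("duplicate sequence id: ", id[duplicated(id)][1])
  if (length(id) && any(!nzchar(residues)))
    stop("empty residue string for record: ", id[!nzchar(residues)][1])
  if (kind == "cds") {
    bad <- nchar(gsub("-", "", residues, fixed = TRUE)) %% 3 != 0
    if (any(bad))
      stop("CDS length not divisible by 3 for record: ", id[bad][1])
  }
  structure(data.frame(id = id, genome_id = genome_id, residues = residues,
                       kind = rep(kind, length(id)),
                       stringsAsFactors = FALSE),
            class = c("seq_records", "data.frame"))
}

#' Read a FASTA file into sequence records
#'
#' Headers are parsed as \code{"id genome=<genome_id>"}; records without a
#' \code{genome=} tag get \code{genome_id = id}. Order-preserving, and
#' round-trips with [write_fasta()] modulo line wrapping.
#'
#' @param path file path.
#' @param kind sequence kind (\code{"protein"}, \code{"cds"}, \code{"rrna"}).
#' @return a \code{seq_records} data frame.
#' @export
read_fasta <- function(path, kind = "protein") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0 || !any(grepl("^>", readLines(path, n = 50))))
    return(sequence_records(character(), character(), character(), kind))
  ss <- Biostrings::readBStringSet(path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  genome <- id
  has <- grepl("genome=\\S+", hdr)
  genome[has] <- sub("^genome=", "", regmatches(hdr, regexpr("genome=\\S+", hdr)))
  sequence_records(id, genome, as.character(ss), kind)
}

#' Write sequence records to FASTA
#'
#' Headers are \code{"id genome=<genome_id>"}; sequences wrapped at 60
#' columns.
#'
#' @param records a \code{seq_records} data frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(sprintf(">%s genome=%s", records$id[i], records$genome_id[i]),
               con)
    s <- records$residues[i]
    starts <- seq(1, nchar(s), 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' Read a Newick tree file
#'
#' Wraps \code{ape::read.tree} with an explicit parenthesis-balance check so
#' malformed input fails with the position of the offending character.
#'
#' @param path file path.
#' @return an \code{ape::phylo} tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced '(': ", depth, " unclosed at end of input")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' Write a tree in Newick format
#' @param tree an \code{ape::phylo} tree.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Construct a validated gene feature table
#'
#' @param df data frame with columns genome_id, contig_id, gene_id, start,
#'   end, strand, annotation, replicon_class (1-based inclusive coordinates).
#' @return data frame of class \code{gene_features}.
#' @export
gene_features <- function(df) {
  miss <- setdiff(FEATURE_COLS, names(df))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  df <- df[FEATURE_COLS]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end))
    stop("start > end for gene: ", df$gene_id[df$start > df$end][1])
  if (any(!df$strand %in% c("+", "-")))
    stop("invalid strand (must be + or -) for gene: ",
         df$gene_id[!df$strand %in% c("+", "-")][1])
  ok <- df$annotation %in% ANNOTATION_VOCAB | grepl("^effector", df$annotation)
  if (any(!ok)) {
    warning("unknown annotation mapped to 'other': ",
            paste(unique(df$annotation[!ok]), collapse = ", "))
    df$annotation[!ok] <- "other"
  }
  rc_ok <- df$replicon_class %in% REPLICON_CLASSES
  if (any(!rc_ok)) {
    warning("unknown replicon_class mapped to 'unknown': ",
            paste(unique(df$replicon_class[!rc_ok]), collapse = ", "))
    df$replicon_class[!rc_ok] <- "unknown"
  }
  class(df) <- c("gene_features", "data.frame")
  df
}

#' Read a gene feature table (TSV with header)
#' @param path file path.
#' @return data frame of class \code{gene_features}.
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  gene_features(df)
}

#' Write a gene feature table as TSV
#' @param features a \code{gene_features} data frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_feature_table <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
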