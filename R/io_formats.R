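#' Read a promoter-enhancer interaction table
#'
#' Parses an interaction table into the canonical internal representation:
#' one row per promoter-enhancer pair with both anchor regions, coordinates
#' converted to 0-based half-open. Exact duplicate pairs are collapsed to a
#' single interaction unless \code{keep_duplicates = TRUE}.
#'
#' Three dialects are supported:
#' \describe{
#'   \item{\code{generic_tsv}}{The canonical format, a header TSV with
#'     columns \code{promoter_id, p_chrom, p_tss, p_strand, enhancer_id,
#'     e_chrom, e_start, e_end}. \code{p_tss} is the 1-based TSS position;
#'     \code{e_start}/\code{e_end} are 1-based inclusive.}
#'   \item{\code{rubin_bed}}{A headerless, 0-based half-open TSV (BED-style
#'     capture Hi-C contact export). Column positions must be supplied via
#'     \code{mapping}, a named list or vector of column indices with names
#'     \code{promoter_id, p_chrom, p_tss, enhancer_id, e_chrom, e_start,
#'     e_end} (and optionally \code{p_strand}). \code{p_tss} here is a
#'     0-based position.}
#'   \item{\code{sahlen_xlsx}}{An XLSX supplementary table with 1-based
#'     coordinates, read via \pkg{readxl}. Column names (or indices) must be
#'     supplied via \code{mapping} with the same names as above; the
#'     published table's layout is not standardized, so no default mapping
#'     is guessed.}
#' }
#'
#' @param path Path to the interaction file.
#' @param dialect One of \code{"generic_tsv"}, \code{"rubin_bed"},
#'   \code{"sahlen_xlsx"}.
#' @param mapping Named list/vector of column indices (or names for xlsx)
#'   required for the \code{rubin_bed} and \code{sahlen_xlsx} dialects.
#' @param keep_duplicates Keep multiplicity of exact duplicate pairs
#'   (default \code{FALSE}: unique interactions).
#' @return A data.frame of class \code{interaction_table} with columns
#'   \code{promoter_id, p_chrom, p_anchor, p_strand, enhancer_id, e_chrom,
#'   e_start, e_end}; \code{p_anchor} is the 0-based TSS position and
#'   \code{e_start}/\code{e_end} are 0-based half-open.
#' @export
read_interaction_table <- function(path,
                                   dialect = c("generic_tsv", "rubin_bed",
                                               "sahlen_xlsx"),
                                   mapping = NULL,
                                   keep_duplicates = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)

  raw <- switch(dialect,
    generic_tsv = {
      df <- utils::read.delim(path, header = TRUE, sep = "\t",
                              colClasses = "character",
                              check.names = FALSE)
      need <- c("promoter_id", "p_chrom", "p_tss", "p_strand",
                "enhancer_id", "e_chrom", "e_start", "e_end")
      miss <- setdiff(need, names(df))
      if (length(miss))
        stop("generic_tsv is missing columns: ", paste(miss, collapse = ", "))
      data.frame(promoter_id = df$promoter_id,
                 p_chrom = df$p_chrom,
                 p_anchor = .num_col(df$p_tss, "p_tss") - 1,  # 1-based -> 0-based
                 p_strand = df$p_strand,
                 enhancer_id = df$enhancer_id,
                 e_chrom = df$e_chrom,
                 e_start = .num_col(df$e_start, "e_start") - 1,
                 e_end = .num_col(df$e_end, "e_end"),
                 stringsAsFactors = FALSE)
    },
    rubin_bed = {
      .check_mapping(mapping)
      df <- utils::read.delim(path, header = FALSE, sep = "\t",
                              colClasses = "character")
      .mapped_table(df, mapping, one_based = FALSE)
    },
    sahlen_xlsx = {
      .check_mapping(mapping)
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("the sahlen_xlsx dialect requires the 'readxl' package")
      df <- as.data.frame(readxl::read_excel(path, col_types = "text"))
      .mapped_table(df, mapping, one_based = TRUE)
    })

  if (nrow(raw) == 0L) stop("no interaction records in ", path)
  bad <- which(raw$promoter_id == "" | raw$enhancer_id == "" |
                 !(raw$e_end > raw$e_start))
  if (length(bad))
    stop("malformed interaction record at row ", bad[1],
         " (empty id or non-positive region width)")

  if (!keep_duplicates) {
    key <- paste(raw$promoter_id, raw$enhancer_id, sep = "\r")
    raw <- raw[!duplicated(key), , drop = FALSE]
  }
  rownames(raw) <- NULL
  class(raw) <- c("interaction_table", "data.frame")
  raw
}

.num_col <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out))
    stop("malformed interaction record at row ", which(is.na(out))[1],
         ": non-numeric ", what)
  out
}

.check_mapping <- function(mapping) {
  need <- c("promoter_id", "p_chrom", "p_tss", "e_chrom", "e_start",
            "e_end")
  if (is.null(mapping) || !all(need %in% names(mapping)))
    stop("this dialect requires a 'mapping' naming columns: ",
         paste(need, collapse = ", "),
         " (enhancer_id and p_strand optional)")
}

# apply a user column mapping; enhancer_id defaults to the coordinate
# string chrom:start-end when the source table carries no enhancer name
.mapped_table <- function(df, mapping, one_based) {
  m <- function(f) df[[mapping[[f]]]]
  off <- if (one_based) 1 else 0
  e_start <- .num_col(m("e_start"), "e_start") - off
  e_end <- .num_col(m("e_end"), "e_end")
  enh_id <- if (!is.null(mapping[["enhancer_id"]])) m("enhancer_id")
            else paste0(m("e_chrom"), ":", e_start, "-", e_end)
  strand <- if (!is.null(mapping[["p_strand"]])) m("p_strand")
            else "unknown"
  data.frame(promoter_id = m("promoter_id"),
             p_chrom = m("p_chrom"),
             p_anchor = .num_col(m("p_tss"), "p_tss") - off,
             p_strand = strand,
             enhancer_id = enh_id,
             e_chrom = m("e_chrom"),
             e_start = e_start,
             e_end = e_end,
             stringsAsFactors = FALSE)
}

#' Read a genome FASTA
#'
#' Reads a (multi-)FASTA into a named \code{DNAStringSet}. Sequences are
#' case-normalized to upper case and multi-line records concatenated.
#'
#' @param path Path to a FASTA file.
#' @return A \code{Biostrings::DNAStringSet}, one element per chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) == 0L) stop("no FASTA records in ", path)
  # keep only the first whitespace-delimited token of each header
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate FASTA header: ",
         names(g)[duplicated(names(g))][1])
  if (any(Biostrings::width(g) == 0L))
    stop("empty sequence for record: ", names(g)[Biostrings::width(g) == 0L][1])
  # DNAStringSet parsing uppercases IUPAC letters already; enforce anyway
  # for genomes written with soft-masked (lower-case) stretches.
  g
}

#' Write a tabular result as TSV
#'
#' All pipeline outputs go through this writer: tab-separated, header line,
#' no quoting, \code{NA}/\code{NaN} serialized as \code{"NA"}, numbers at
#' full precision (15 significant digits) so values round-trip.
#'
#' @param table A data.frame (or coercible).
#' @param path Output path.
#' @export
write_tsv <- function(table, path) {
  table <- as.data.frame(table)
  if (anyDuplicated(names(table)))
    stop("duplicate column names: ",
         names(table)[duplicated(names(table))][1])
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], function(x) {
    ifelse(is.na(x), NA_character_, format(x, digits = 15, trim = TRUE,
                                           scientific = NA))
  })
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(NULL)
}

#' Read a TSV written by \code{write_tsv}
#'
#' @param path Input path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = "NA")
}
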