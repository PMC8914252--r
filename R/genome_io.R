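# Readers/writers for the standard formats the pipeline touches, plus the
# replicon registry holding ori/ter geometry. Internal convention is
# 0-based half-open everywhere; GFF3 (1-based inclusive) is converted at
# this boundary and nowhere else.

#' Build a replicon registry
#'
#' A replicon is a circular DNA molecule with a bidirectional replication
#' origin (`ori`) and terminus (`ter`). The registry is a data.frame with
#' one row per replicon and an optional sequence column.
#'
#' @param name character vector of replicon identifiers.
#' @param length integer lengths in bp (> 0).
#' @param ori,ter 0-based coordinates of the replication origin and
#'   terminus; `ori != ter` within a replicon.
#' @param sequence optional character vector of DNA strings over
#'   `{A,C,G,T,N}`, each of exactly `length` characters (or `NA`).
#' @return data.frame of class `replicon_set` with columns
#'   `name, length, ori, ter, sequence`.
#' @export
replicon_set <- function(name, length, ori, ter, sequence = NULL) {
  length <- as.numeric(length); ori <- as.numeric(ori); ter <- as.numeric(ter)
  stopifnot(!anyDuplicated(name), all(length > 0),
            all(ori >= 0 & ori < length), all(ter >= 0 & ter < length),
            all(ori != ter))
  if (is.null(sequence)) sequence <- rep(NA_character_, base::length(name))
  ok <- is.na(sequence) | nchar(sequence) == length
  if (!all(ok)) {
    stop_format("sequence length mismatch for replicon '%s'", name[!ok][1])
  }
  bad <- !is.na(sequence) & grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop_format("replicon '%s': sequence has characters outside {A,C,G,T,N}",
                name[bad][1])
  }
  out <- data.frame(name = name, length = length, ori = ori, ter = ter,
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("replicon_set", "data.frame")
  out
}

replicon_row <- function(replicons, name) {
  i <- match(name, replicons$name)
  if (is.na(i)) stop_format("unknown replicon '%s'", name)
  replicons[i, , drop = FALSE]
}

#' Enumerate the 18 sequencing library keys
#'
#' Three plasmid constructs (tagged active RNPs, tagged IEP without the
#' ribozyme, untagged active RNPs) times two fractions (input, IP) times
#' three biological replicates.
#'
#' @return data.frame with columns `construct, fraction, replicate, key`.
#' @export
library_keys <- function() {
  g <- expand.grid(
    replicate = 1:3,
    fraction  = c("input", "IP"),
    construct = c("pKG4_FlagIEP", "pKG_FlagIEP", "pKGEMA4"),
    stringsAsFactors = FALSE)
  g <- g[, c("construct", "fraction", "replicate")]
  g$key <- paste(g$construct, g$fraction, g$replicate, sep = ".")
  g
}

## ---- FASTA ----------------------------------------------------------------

#' Read a FASTA file into a named vector of DNA strings
#'
#' Sequences are uppercased and validated against the `{A,C,G,T,N}`
#' alphabet; record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop_format("FASTA file has no records: %s", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs))) {
    stop_format("empty FASTA record '%s'", names(seqs)[!nzchar(seqs)][1])
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop_format("FASTA record '%s': illegal character '%s' at position %d",
                names(seqs)[i], substr(seqs[i], bad[i], bad[i]), bad[i])
  }
  seqs
}

#' Write DNA strings to a FASTA file
#'
#' @param seqs named character vector of DNA strings.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

## ---- GFF3 -----------------------------------------------------------------

#' Read gene annotations from a GFF3 file
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention at this boundary.
#'
#' @param path path to a GFF3 file.
#' @param types feature types to retain (default `gene` and `CDS`).
#' @return data.frame with columns `replicon, start, end, strand, gene_id`.
#' @export
read_gff3 <- function(path, types = c("gene", "CDS")) {
  if (!file.exists(path)) stop_format("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% types]
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop_format("GFF3 record with unsupported strand '%s'",
                strand[!strand %in% c("+", "-")][1])
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- paste0("feature_", seq_along(gr))
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  out <- data.frame(
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    gene_id = as.character(ids),
    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) {
    stop_format("GFF3 feature '%s' has end <= start",
                out$gene_id[out$end <= out$start][1])
  }
  out
}

#' Write gene annotations to GFF3
#'
#' @param genes data.frame as returned by [read_gff3()].
#' @param path output path.
#' @param type feature type to emit (default `"gene"`).
#' @param source source column value.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, type = "gene", source = "rnpchip") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- type
  gr$source <- source
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## ---- BED ------------------------------------------------------------------

#' Read a BED3+ file
#'
#' BED is 0-based half-open, matching the internal convention; no
#' conversion is applied. Lines starting with `#` or `track` are skipped.
#'
#' @param path path to a BED file.
#' @return data.frame with columns `replicon, start, end` and, when
#'   present, `name, score, strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_format("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(replicon = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  cols <- c("replicon", "start", "end", "name", "score", "strand")
  k <- seq_len(min(ncol(dt), 6))
  data.table::setnames(dt, k, cols[k])
  df <- as.data.frame(dt)
  if (!is.numeric(df$start) || !is.numeric(df$end) ||
      any(df$start != floor(df$start)) || any(df$end != floor(df$end))) {
    stop_format("BED file %s: non-integer coordinates", path)
  }
  if (any(df$start >= df$end)) {
    stop_format("BED file %s: start >= end at line %d", path,
                which(df$start >= df$end)[1])
  }
  df
}

#' Write intervals to a BED file
#'
#' Columns beyond `replicon, start, end` among `name, score, strand` are
#' written when present. An optional `#` comment header records run
#' provenance.
#'
#' @param df data.frame with at least `replicon, start, end`.
#' @param path output path.
#' @param header optional character vector of comment lines (written with
#'   a leading `#`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, header = NULL) {
  cols <- intersect(c("replicon", "start", "end", "name", "score", "strand"),
                    names(df))
  stopifnot(all(c("replicon", "start", "end") %in% cols))
  # BED columns are positional: truncate at the first absent optional column
  want <- c("replicon", "start", "end", "name", "score", "strand")
  keep <- want[seq_len(max(which(want %in% cols)))]
  out <- df[, keep[keep %in% cols], drop = FALSE]
  writeLines(if (is.null(header)) character(0) else paste0("#", header),
             path)
  if (nrow(out) > 0) {
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                       append = TRUE, scipen = 50)
  }
  invisible(path)
}

## ---- replicon config ------------------------------------------------------

#' Read a replicon configuration table
#'
#' A flat whitespace/tab-separated file with a header and columns
#' `name length ori ter` describing each circular replicon.
#'
#' @param path path to the config file.
#' @return a [replicon_set()] (without sequences).
#' @export
read_replicon_config <- function(path) {
  if (!file.exists(path)) stop_format("replicon config not found: %s", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  stopifnot(all(c("name", "length", "ori", "ter") %in% names(df)))
  replicon_set(df$name, df$length, df$ori, df$ter)
}

#' Write a replicon configuration table
#'
#' @param replicons a [replicon_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_replicon_config <- function(replicons, path) {
  utils::write.table(replicons[, c("name", "length", "ori", "ter")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
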