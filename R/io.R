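# File input/output: FASTA/FASTQ via Biostrings for parsing; writing is done
# with plain connections so that output bytes are an auditable function of the
# data (determinism contract of the simulator and CLI).

#' Read a mature miRNA FASTA file
#'
#' @param path FASTA file.
#' @param u_to_t convert U to T (RNA-alphabet releases of mature miRNAs).
#' @return data.frame with columns `mirna_id`, `sequence` (DNA alphabet).
#' @export
read_mirna_fasta <- function(path, u_to_t = TRUE) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  if (u_to_t) seqs <- rna_to_dna(seqs)
  if (anyDuplicated(ids))
    stop("duplicate ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  .check_dna(seqs, sprintf("FASTA %s", basename(path)))
  data.frame(mirna_id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a reference set as FASTA
#'
#' By default writes the mature (canonical) sequences only — the form the
#' counting stage consumes, which derives the "+A" counterpart itself. With
#' `what = "paired"` both collections are written; adenylated records carry a
#' `_plusA` id suffix.
#'
#' @param refset a [reference_set].
#' @param path output file.
#' @param what `"mature"` (default) or `"paired"`.
#' @return invisibly, `path`.
#' @export
write_reference_fasta <- function(refset, path,
                                  what = c("mature", "paired")) {
  stopifnot(inherits(refset, "reference_set"))
  what <- match.arg(what)
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- c(rbind(paste0(">", refset$canonical$mirna_id),
                   refset$canonical$sequence))
  if (what == "paired")
    lines <- c(lines,
               rbind(paste0(">", refset$adenylated$mirna_id, "_plusA"),
                     refset$adenylated$sequence))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write reads as FASTQ with a constant quality line
#'
#' @param reads character vector of read sequences.
#' @param path output file (use [gzip] for `.fastq.gz`).
#' @param id_prefix read id prefix; ids are `prefix.read1`, `prefix.read2`, ...
#' @param quality_char single character used for every base quality.
#' @param gzip write gzip-compressed output.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path, id_prefix = "read", quality_char = "I",
                        gzip = FALSE) {
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(reads)) {
    ids <- paste0("@", id_prefix, ".read", seq_along(reads))
    qual <- strrep(quality_char, nchar(reads))
    writeLines(c(rbind(ids, reads, "+", qual)), con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file into a character vector of sequences
#'
#' @param path FASTQ (optionally gzip-compressed) file.
#' @return character vector of read sequences, named by read id.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such FASTQ file: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                 error = function(e)
                   stop("failed to parse FASTQ ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write a count table as TSV
#'
#' One row per miRNA, paired columns `<sample>.canonical` and
#' `<sample>.adenylated`, matching the dual-reference counting output.
#'
#' @param counts a [count_table] (or compatible list).
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_count_table <- function(counts, path) {
  can <- counts$canonical
  ade <- counts$adenylated
  samples <- colnames(can)
  out <- data.frame(mirna_id = rownames(can), stringsAsFactors = FALSE)
  for (s in samples) {
    out[[paste0(s, ".canonical")]] <- can[, s]
    out[[paste0(s, ".adenylated")]] <- ade[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path TSV file.
#' @return a [count_table] (without per-sample assignment totals).
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ccols <- grep("\\.canonical$", names(df), value = TRUE)
  samples <- sub("\\.canonical$", "", ccols)
  can <- as.matrix(df[, paste0(samples, ".canonical"), drop = FALSE])
  ade <- as.matrix(df[, paste0(samples, ".adenylated"), drop = FALSE])
  dimnames(can) <- dimnames(ade) <- list(df$mirna_id, samples)
  structure(list(canonical = can, adenylated = ade, totals = NULL),
            class = "count_table")
}

#' Read a Ct table from CSV/TSV (wide: targets x samples)
#'
#' The first column holds target ids; remaining columns are samples. Group
#' labels come from a separate design table (sample, group).
#'
#' @param path CSV or TSV file (delimiter sniffed from the extension).
#' @param design data.frame with columns `sample` and `group`, or path to one.
#' @param internal_control id of the internal-control row (e.g. "U6").
#' @return a [ct_table].
#' @export
read_ct_table <- function(path, design, internal_control = "U6") {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (is.character(design)) {
    dsep <- if (grepl("\\.tsv$|\\.txt$", design)) "\t" else ","
    design <- utils::read.table(design, sep = dsep, header = TRUE,
                                stringsAsFactors = FALSE)
  }
  groups <- stats::setNames(design$group, design$sample)
  ct_table(m, groups = groups[colnames(m)],
           internal_control = internal_control)
}
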