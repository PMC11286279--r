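# Readers and writers ----------------------------------------------------

#' Read a string collection from a file
#'
#' Reads FASTA, FASTQ or plain one-sequence-per-line text into a
#' [string_collection]. Records are ingested in file order (the
#' significant default for the order-dependent variants) and may then be
#' reordered by a named policy. FASTQ quality lines are discarded.
#' Records containing a reserved sentinel glyph are rejected with the
#' record name.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (default; by extension, falling back to content
#'   sniffing), `"fasta"`, `"fastq"`, or `"lines"`.
#' @param case `"preserve"` (default; transforms are exact character
#'   permutations of their input) or `"upper"`.
#' @param order Reordering policy: `"file"` (default), `"lex"`,
#'   `"colex"`, `"opt"`, or an integer permutation / permutation file
#'   (one 1-based index per line) via `order_file`.
#' @param order_file Optional path to a permutation file.
#' @return A [string_collection].
#' @export
read_collection <- function(path, format = c("auto", "fasta", "fastq", "lines"),
                            case = c("preserve", "upper"),
                            order = c("file", "lex", "colex", "opt"),
                            order_file = NULL) {
  format <- match.arg(format)
  case <- match.arg(case)
  if (!file.exists(path)) stop("cannot read '", path, "'")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("fa", "fasta", "fna", "ffn", "faa")) "fasta"
      else if (ext %in% c("fq", "fastq")) "fastq"
      else {
        first <- readLines(path, n = 1L)
        if (length(first) == 0L) stop("empty input file: ", path)
        if (startsWith(first, ">")) "fasta"
        else if (startsWith(first, "@")) "fastq" else "lines"
      }
  }
  if (format %in% c("fasta", "fastq")) {
    set <- Biostrings::readBStringSet(path, format = format)
    if (length(set) == 0L) stop("empty input file: ", path)
    strings <- as.character(set)
    ids <- names(set)
  } else {
    strings <- readLines(path)
    strings <- strings[nzchar(strings)]
    if (length(strings) == 0L) stop("empty input file: ", path)
    ids <- as.character(seq_along(strings))
  }
  if (any(!nzchar(strings)))
    stop("empty record in '", path, "': ",
         ids[which(!nzchar(strings))[1L]])
  if (case == "upper") strings <- toupper(strings)
  bad <- grepl(SEPARATOR, strings, fixed = TRUE) |
    grepl(TERMINATOR, strings, fixed = TRUE)
  if (any(bad))
    stop("record contains a reserved sentinel glyph ('$' or '#'): ",
         ids[which(bad)[1L]])
  m <- string_collection(strings)
  message(sprintf("read %d sequence(s), total length %d, alphabet size %d",
                  m$k, m$total_length, m$sigma))
  if (!is.null(order_file)) {
    perm <- as.integer(readLines(order_file))
    return(apply_order(m, perm))
  }
  order <- match.arg(order)
  switch(order,
         file = m,
         lex = apply_order(m, lex_order(m)),
         colex = apply_order(m, colex_order(m)),
         opt = apply_order(m, opt_order(m)))
}

#' Write a transform text
#'
#' @param t A `bwt_transform` (or a bare string).
#' @param path Output path.
#' @param format `"text"` (single line) or `"rle"` (TSV of
#'   symbol/run-length pairs, one row per run).
#' @return Invisibly, the path.
#' @export
write_transform <- function(t, path, format = c("text", "rle")) {
  format <- match.arg(format)
  text <- if (inherits(t, "bwt_transform")) t$text else as.character(t)
  if (format == "text") {
    writeLines(text, path)
  } else {
    r <- rle(str_chars(text))
    utils::write.table(data.frame(symbol = r$values, length = r$lengths),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write conjugate ranks alongside an eBWT
#'
#' One integer per input string (the omega-rank of its offset-0
#' conjugate), the sidecar that makes the eBWT text reversible.
#'
#' @param t A `bwt_transform` of variant `"ebwt"`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_conjugate_ranks <- function(t, path) {
  stopifnot(inherits(t, "bwt_transform"), t$variant == "ebwt")
  writeLines(as.character(t$conjugate_ranks), path)
  invisible(path)
}

#' Write a collection as FASTA or plain lines
#'
#' @param x A [string_collection], `bwt_inversion`, or character vector.
#' @param path Output path.
#' @param format `"fasta"` or `"lines"`.
#' @param prefix Header prefix for generated FASTA names.
#' @return Invisibly, the path.
#' @export
write_collection <- function(x, path, format = c("fasta", "lines"),
                             prefix = "seq") {
  format <- match.arg(format)
  strings <- if (inherits(x, "string_collection")) x$strings
    else if (inherits(x, "bwt_inversion")) x$strings
    else as.character(x)
  if (format == "lines") {
    writeLines(strings, path)
  } else {
    set <- Biostrings::BStringSet(strings)
    names(set) <- paste0(prefix, seq_along(strings))
    Biostrings::writeXStringSet(set, path)
  }
  invisible(path)
}

#' Write a comparison report
#'
#' @param report A `bwt_comparison` from [compare_all].
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  stopifnot(inherits(report, "bwt_comparison"))
  format <- match.arg(format)
  summ <- comparison_summary(report)
  if (format == "json") {
    out <- c(summ, list(
      "runs per variant" = as.list(report$runs),
      "n/r per variant" = as.list(report$n_over_r),
      "pairwise normalized Hamming" = report$hamming_normalized,
      "edit distance vs eBWT" = as.list(report$edit_vs_ebwt),
      "edit-distance subsample size" = report$subsample_size))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    df <- data.frame(statistic = names(summ),
                     value = vapply(summ, function(v) format(v, digits = 10), ""))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
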