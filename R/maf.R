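#' Multiple alignment block (MAF)
#'
#' One alignment block of a UCSC-style multiple alignment format file.
#' Each record is one species row: `src` is "species.chrom", `start` is
#' the 0-based offset of the aligned fragment on the + strand of the
#' source sequence, `size` its ungapped length, and `text` the aligned
#' sequence including '-' gap characters. The first record is the
#' reference (e.g. human) row.
#'
#' @param records data.frame with columns `src`, `start`, `size`,
#'   `strand`, `srcSize`, `text`.
#' @param score optional block score.
#' @return an object of class `maf_block` with derived columns `species`
#'   and `seqid` split from `src` on the first '.'.
#' @export
new_maf_block <- function(records, score = 0) {
  stopifnot(is.data.frame(records),
            all(c("src", "start", "size", "strand", "srcSize", "text")
                %in% names(records)))
  widths <- nchar(records$text)
  if (length(unique(widths)) != 1L)
    stop("all aligned sequences in a MAF block must have equal length; got ",
         paste(unique(widths), collapse = ", "))
  ungapped <- nchar(gsub("-", "", records$text, fixed = TRUE))
  bad <- which(ungapped != records$size)
  if (length(bad))
    stop("MAF record ", records$src[bad[1L]],
         ": ungapped length ", ungapped[bad[1L]],
         " != stated size ", records$size[bad[1L]])
  records$text <- toupper(records$text)
  records$species <- sub("\\..*$", "", records$src)
  records$seqid <- sub("^[^.]*\\.", "", records$src)
  structure(list(records = records, score = score), class = "maf_block")
}

#' @export
print.maf_block <- function(x, ...) {
  cat("<maf_block> ", nrow(x$records), " species, width ",
      nchar(x$records$text[1L]), ", reference ", x$records$src[1L],
      "\n", sep = "")
  invisible(x)
}

#' Read a MAF file
#'
#' Parses a UCSC-dialect multiple alignment format file into a list of
#' [new_maf_block()] objects, in file order. Soft-masked lowercase is
#' uppercased; gap-only columns are preserved as written.
#'
#' @param path MAF text file.
#' @return list of `maf_block` objects.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  cur_score <- 0
  flush <- function() {
    if (!is.null(cur) && length(cur)) {
      df <- do.call(rbind, cur)
      blocks[[length(blocks) + 1L]] <<- new_maf_block(df, score = cur_score)
    }
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^#", line)) next
    if (!nzchar(trimws(line))) { flush(); next }
    first <- substr(line, 1L, 1L)
    if (first == "a") {
      flush()
      cur <- list()
      sc <- sub(".*score=([-0-9.eE+]+).*", "\\1", line)
      cur_score <- if (sc != line) as.numeric(sc) else 0
    } else if (first == "s") {
      if (is.null(cur))
        stop("MAF parse error at line ", i, ": 's' line outside a block")
      toks <- strsplit(trimws(line), "\\s+")[[1L]]
      if (length(toks) != 7L)
        stop("MAF parse error at line ", i, ": expected 7 fields, got ",
             length(toks))
      start <- suppressWarnings(as.numeric(toks[3L]))
      size <- suppressWarnings(as.numeric(toks[4L]))
      srcSize <- suppressWarnings(as.numeric(toks[6L]))
      if (anyNA(c(start, size, srcSize)))
        stop("MAF parse error at line ", i, ": non-numeric coordinate")
      cur[[length(cur) + 1L]] <- data.frame(
        src = toks[2L], start = start, size = size, strand = toks[5L],
        srcSize = srcSize, text = toks[7L], stringsAsFactors = FALSE)
    }
    # 'i'/'e'/'q' lines are metadata; skipped
  }
  flush()
  blocks
}

#' Write MAF blocks to a file
#' @param blocks list of [new_maf_block()] objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines(paste0("a score=", format(b$score)), con)
    r <- b$records
    writeLines(sprintf("s %s %d %d %s %d %s",
                       r$src, as.integer(r$start), as.integer(r$size),
                       r$strand, as.integer(r$srcSize), r$text), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Binding-site records
#'
#' A plain data.frame carrier for binding-site loci: promoter/gene id,
#' 0-based half-open coordinates on the promoter, strand, motif id and
#' (optionally) the site sequence.
#'
#' @param promoter character vector of promoter/gene ids.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand "+" or "-".
#' @param motif motif id per site.
#' @param seq optional site sequences.
#' @return data.frame of class `site_records`.
#' @export
site_records <- function(promoter, start, end, strand = "+", motif,
                         seq = NA_character_) {
  if (any(start < 0) || any(end <= start))
    stop("site coordinates must satisfy 0 <= start < end")
  df <- data.frame(promoter = promoter, start = as.integer(start),
                   end = as.integer(end), strand = strand, motif = motif,
                   seq = seq, stringsAsFactors = FALSE)
  class(df) <- c("site_records", "data.frame")
  df
}

#' Write site records as BED6
#'
#' Columns: promoter id, start, end, motif id, score 0, strand;
#' coordinates 0-based half-open as in the BED convention.
#'
#' @param records a [site_records()] data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sites_bed <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records))
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       records$promoter, records$start, records$end,
                       records$motif, records$strand), con)
  invisible(path)
}

#' Read a BED6 file of site records
#' @param path BED6 file as written by [write_sites_bed()].
#' @return a [site_records()] data.frame (empty if the file is empty).
#' @export
read_sites_bed <- function(path) {
  if (file.size(path) == 0)
    return(site_records(character(), integer(), integer(),
                        character(), character(), character()))
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("promoter", "start", "end", "motif",
                                 "score", "strand"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric", "character"))
  site_records(df$promoter, df$start, df$end, df$strand, df$motif)
}
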