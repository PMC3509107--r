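#' @useDynLib motifforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd setNames quantile phyper p.adjust runif
#' @importFrom utils write.table read.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' A PWM is a 4 x m column-stochastic matrix of base probabilities
#' (rows A, C, G, T), the standard representation of a transcription
#' factor's binding preference.
#'
#' @param matrix numeric 4 x m matrix; columns must sum to 1.
#'   Rows are taken in A, C, G, T order (rownames, if present, are checked).
#' @param id identifier string (e.g. a JASPAR accession such as "MA0142.1").
#' @param pseudocount probability mass that was added per cell when the
#'   matrix was built from counts; recorded for provenance.
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(matrix, id = "pwm", pseudocount = 0) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L)
    stop("a PWM must have exactly 4 rows (A, C, G, T)")
  if (!is.null(rownames(matrix))) {
    if (!setequal(rownames(matrix), DNA_BASES))
      stop("PWM rownames must be A, C, G, T")
    matrix <- matrix[DNA_BASES, , drop = FALSE]
  } else {
    rownames(matrix) <- DNA_BASES
  }
  if (ncol(matrix) < 1L) stop("a PWM needs at least one column")
  if (any(matrix < 0)) stop("PWM entries must be non-negative")
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-9))
    stop("every PWM column must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  structure(list(matrix = matrix, id = id, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$id, ": ", ncol(x$matrix), " columns, consensus ",
      pwm_consensus(x), "\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' @rdname new_pwm
#' @param x object to test.
#' @export
is_pwm <- function(x) inherits(x, "pwm")

#' Number of columns of a PWM
#' @param pwm a [new_pwm()] object.
#' @return integer motif length m.
#' @export
pwm_length <- function(pwm) ncol(pwm$matrix)

#' Consensus sequence of a PWM (highest-probability base per column,
#' ties to the earlier base in A,C,G,T order)
#' @param pwm a [new_pwm()] object.
#' @return character scalar of length m.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$matrix, 2L, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param pwm a [new_pwm()] object.
#' @return the PWM describing binding on the opposite strand.
#' @export
pwm_revcomp <- function(pwm) {
  m <- pwm$matrix[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$matrix))),
                  drop = FALSE]
  rownames(m) <- DNA_BASES
  new_pwm(m, id = pwm$id, pseudocount = pwm$pseudocount)
}

#' Build a PWM from a count matrix
#'
#' Adds `pseudocount` to every cell, then normalises each column to sum
#' to 1. With pseudocount 0 the conversion is scale invariant.
#'
#' @param counts 4 x m non-negative count matrix (rows A, C, G, T).
#' @param id identifier.
#' @param pseudocount additive pseudocount per cell (default 0.01).
#' @return a [new_pwm()] object.
#' @export
pwm_from_counts <- function(counts, id = "pwm", pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts in matrix '", id, "'")
  counts <- counts + pseudocount
  cs <- colSums(counts)
  if (any(cs == 0))
    stop("zero-sum column in matrix '", id,
         "' and pseudocount is 0; cannot normalise")
  new_pwm(sweep(counts, 2L, cs, "/"), id = id, pseudocount = pseudocount)
}

#' Build a PWM from aligned site sequences
#'
#' Per-column base frequencies over a set of equal-length sequences, with
#' an additive pseudocount.
#'
#' @param seqs character vector of equal-length sequences over A,C,G,T.
#' @param id identifier.
#' @param pseudocount additive pseudocount per cell (default 0.01).
#' @return a [new_pwm()] object.
#' @export
build_pwm <- function(seqs, id = "pwm", pseudocount = 0.01) {
  if (length(seqs) < 1L) stop("need at least one sequence")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have mixed lengths: ", paste(unique(lens), collapse = ", "))
  m <- lens[1L]
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), ncol = m, byrow = TRUE)
  counts <- vapply(seq_len(m), function(j) {
    tabulate(match(chars[, j], DNA_BASES), nbins = 4L)
  }, numeric(4L))
  counts <- matrix(counts, nrow = 4L, dimnames = list(DNA_BASES, NULL))
  pwm_from_counts(counts, id = id, pseudocount = pseudocount)
}

#' Per-column Shannon entropy of a PWM, in bits
#' @param pwm a [new_pwm()] object.
#' @return numeric vector of length m; each value in \[0, 2\] bits.
#' @export
entropy_curve <- function(pwm) {
  p <- pwm$matrix
  pl <- ifelse(p > 0, p * log2(p), 0)
  -colSums(pl)
}

#' Average entropy of a PWM, in bits
#'
#' The mean over columns of the per-column Shannon entropy,
#' E = -(1/m) sum_j sum_b p_bj log2 p_bj, with 0 log 0 := 0. Used as the
#' tie-break when ranking motif clusters: at equal rank score, the sharper
#' (lower-entropy) motif ranks first.
#'
#' @param pwm a [new_pwm()] object.
#' @return numeric scalar in \[0, 2\].
#' @export
average_entropy <- function(pwm) mean(entropy_curve(pwm))

#' Draw one site sequence from a PWM
#'
#' Each base is drawn independently from its column distribution, using
#' the current R random number generator state.
#'
#' @param pwm a [new_pwm()] object.
#' @return character scalar of length m.
#' @export
sample_site <- function(pwm) {
  m <- ncol(pwm$matrix)
  idx <- vapply(seq_len(m), function(j) {
    sample.int(4L, 1L, prob = pwm$matrix[, j])
  }, integer(1L))
  paste(DNA_BASES[idx], collapse = "")
}

#' Shuffle PWM entries within each column
#'
#' The random-control construction used to estimate chance matching:
#' within each column the 4 probabilities are permuted independently,
#' preserving the per-column value multiset (hence per-column entropy)
#' and the column order, while destroying base identity.
#'
#' @param pwm a [new_pwm()] object.
#' @param seed optional integer; when given, shuffling is deterministic
#'   and the caller's RNG state is left untouched.
#' @return a shuffled [new_pwm()] object with id suffixed "_shuf".
#' @export
shuffle_pwm_columns <- function(pwm, seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  m <- apply(pwm$matrix, 2L, function(col) col[sample.int(4L)])
  rownames(m) <- DNA_BASES
  new_pwm(m, id = paste0(pwm$id, "_shuf"), pseudocount = pwm$pseudocount)
}

#' Read a collection of PWMs from a matrix text file
#'
#' Supported dialects:
#' \describe{
#'   \item{jaspar-counts}{`>ID name` header, then 4 lines
#'     `A [ 1 2 3 ]` (counts; brackets optional).}
#'   \item{transfac-counts}{records with `ID`/`AC` headers, `P0` column
#'     header, numbered position rows `01  A C G T  consensus`, `//`
#'     separator.}
#'   \item{probability-table}{`>ID` header then 4 whitespace-separated rows
#'     A, C, G, T of probabilities (already column-stochastic).}
#' }
#' Count dialects are converted to probabilities with an additive
#' pseudocount per cell.
#'
#' @param path file path.
#' @param dialect one of "jaspar-counts", "transfac-counts",
#'   "probability-table".
#' @param pseudocount additive pseudocount (default 0.01); ignored for
#'   probability tables.
#' @return list of [new_pwm()] objects.
#' @export
read_pwm_collection <- function(path,
                                dialect = c("jaspar-counts",
                                            "transfac-counts",
                                            "probability-table"),
                                pseudocount = 0.01) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  switch(dialect,
    "jaspar-counts" = parse_jaspar(lines, pseudocount, prob = FALSE),
    "probability-table" = parse_jaspar(lines, pseudocount = 0, prob = TRUE),
    "transfac-counts" = parse_transfac(lines, pseudocount))
}

parse_jaspar <- function(lines, pseudocount, prob) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no '>' headers found")
  out <- vector("list", length(heads))
  ends <- c(heads[-1L] - 1L, length(lines))
  for (i in seq_along(heads)) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    body <- lines[(heads[i] + 1L):ends[i]]
    if (length(body) != 4L)
      stop("matrix '", id, "': expected 4 base rows, got ", length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("[][]", " ", l)
      toks <- strsplit(trimws(l), "\\s+")[[1L]]
      base <- NA_character_
      if (toks[1L] %in% DNA_BASES) {
        base <- toks[1L]
        toks <- toks[-1L]
      }
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals)) stop("matrix '", id, "': non-numeric entries")
      list(base = base, vals = vals)
    })
    bases <- vapply(rows, `[[`, character(1L), "base")
    mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(mat) <- if (anyNA(bases)) DNA_BASES else bases
    mat <- mat[DNA_BASES, , drop = FALSE]
    out[[i]] <- if (prob) new_pwm(mat, id = id, pseudocount = 0)
                else pwm_from_counts(mat, id = id, pseudocount = pseudocount)
  }
  out
}

parse_transfac <- function(lines, pseudocount) {
  out <- list()
  id <- NULL
  rows <- list()
  col_order <- DNA_BASES
  flush <- function() {
    if (length(rows) == 0L) return(invisible(NULL))
    mat <- t(do.call(rbind, rows))
    rownames(mat) <- col_order
    mat <- mat[DNA_BASES, , drop = FALSE]
    out[[length(out) + 1L]] <<-
      pwm_from_counts(mat, id = id %||% paste0("M", length(out) + 1L),
                      pseudocount = pseudocount)
    rows <<- list()
    id <<- NULL
  }
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line)) next
    tag <- sub("^(\\S+).*$", "\\1", line)
    if (tag == "//") { flush(); next }
    if (tag %in% c("ID", "AC", "NA")) {
      if (is.null(id)) id <- sub("^\\S+\\s+", "", line)
      next
    }
    if (tag == "P0" || tag == "PO") {
      col_order <- strsplit(sub("^\\S+\\s+", "", line), "\\s+")[[1L]][1:4]
      next
    }
    if (grepl("^[0-9]+$", tag)) {
      toks <- strsplit(line, "\\s+")[[1L]]
      vals <- suppressWarnings(as.numeric(toks[2:5]))
      if (anyNA(vals)) stop("TRANSFAC row '", line, "': non-numeric counts")
      rows[[length(rows) + 1L]] <- vals
    }
  }
  flush()
  out
}

#' Write PWMs in JASPAR-style probability-table format
#' @param pwms list of [new_pwm()] objects.
#' @param path output file.
#' @param digits significant digits (default 6).
#' @return invisibly, `path`.
#' @export
write_pwm_collection <- function(pwms, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id), con)
    for (b in DNA_BASES) {
      writeLines(paste(b, paste(signif(p$matrix[b, ], digits),
                                collapse = " ")), con)
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leveled plain-text logging
#'
#' Writes a timestamp-free log line to stderr when `level` is at or
#' above the threshold in `options(motifforge.log_level)` ("debug",
#' "info" (default), "warn", or "off"). Timestamps are deliberately
#' omitted so that captured logs are reproducible.
#'
#' @param level one of "debug", "info", "warn".
#' @param ... message parts, pasted together.
#' @return invisibly, TRUE if the line was emitted.
#' @export
mf_log <- function(level = c("info", "debug", "warn"), ...) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warn = 3L, off = 4L)
  threshold <- getOption("motifforge.log_level", "info")
  if (ranks[[level]] < ranks[[threshold]]) return(invisible(FALSE))
  message(sprintf("[%s] %s", toupper(level), paste0(...)))
  invisible(TRUE)
}
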