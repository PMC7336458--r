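#' Read and write PAF alignment tables
#'
#' The minimap2 PAF dialect: 12 mandatory tab-separated columns
#' (`qname`, `qlen`, `qstart`, `qend`, `strand`, `tname`, `tlen`, `tstart`,
#' `tend`, `nmatch`, `alnlen`, `mapq`); any trailing tag columns are ignored
#' on input. Coordinates are 0-based half-open on the forward strand of each
#' sequence.
#'
#' @param path File path.
#' @param paf A PAF tibble.
#' @return `read_paf()` returns a tibble with the 12 mandatory columns;
#'   `write_paf()` returns `path` invisibly.
#' @export
read_paf <- function(path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand",
            "tname", "tlen", "tstart", "tend", "nmatch", "alnlen", "mapq")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_paf())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 12L
  if (any(short)) {
    abort(sprintf("malformed PAF: line %d has fewer than 12 columns",
                  which(short)[1L]))
  }
  m <- t(vapply(parts, function(p) p[1:12], character(12L)))
  colnames(m) <- cols
  df <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  num <- setdiff(cols, c("qname", "strand", "tname"))
  df[num] <- lapply(df[num], function(x) as.integer(as.numeric(x)))
  validate_paf(df)
  df
}

#' @rdname read_paf
#' @export
write_paf <- function(paf, path) {
  validate_paf(paf)
  write.table(paf[, paf_cols()], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

paf_cols <- function() {
  c("qname", "qlen", "qstart", "qend", "strand",
    "tname", "tlen", "tstart", "tend", "nmatch", "alnlen", "mapq")
}

empty_paf <- function() {
  tibble(
    qname = character(), qlen = integer(), qstart = integer(),
    qend = integer(), strand = character(), tname = character(),
    tlen = integer(), tstart = integer(), tend = integer(),
    nmatch = integer(), alnlen = integer(), mapq = integer()
  )
}

validate_paf <- function(paf) {
  if (!all(paf_cols() %in% names(paf))) {
    abort("PAF table is missing mandatory columns")
  }
  if (nrow(paf) == 0L) return(invisible(paf))
  bad <- paf$qstart < 0L | paf$qstart >= paf$qend | paf$qend > paf$qlen |
    paf$tstart < 0L | paf$tstart >= paf$tend | paf$tend > paf$tlen |
    paf$nmatch > paf$alnlen | !(paf$strand %in% c("+", "-"))
  if (any(bad)) {
    abort(sprintf("invalid PAF record at row %d", which(bad)[1L]))
  }
  invisible(paf)
}
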