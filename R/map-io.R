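#' Read and write optical maps
#'
#' Two plain-text formats are supported. The canonical map format stores one
#' map per block: a header line `>map_id enzyme` followed by one line of
#' whitespace-separated fragment lengths. The TSV dialect stores one map per
#' row with columns `map_id`, `enzyme`, `fragments` (comma-joined lengths)
#' and, when any fragment is colored, a fourth column `colors` (comma-joined
#' integer colors, `NA` for uncolored fragments).
#'
#' @param maps A tibble of optical maps (see [optical_map()]).
#' @param path File path.
#' @return `write_maps()`/`write_maps_tsv()` return `path` invisibly;
#'   `read_maps()`/`read_maps_tsv()` return a tibble of optical maps.
#' @name map_io
NULL

#' @rdname map_io
#' @export
write_maps <- function(maps, path) {
  blocks <- purrr::map_chr(split_maps(maps), function(m) {
    paste0(
      ">", m$map_id[1L], " ", m$enzyme[1L], "\n",
      paste(format_len(m$length), collapse = " ")
    )
  })
  writeLines(blocks, path)
  invisible(path)
}

#' @rdname map_io
#' @export
read_maps <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(optical_map("x", "e", 1)[0, ])
  hdr <- grepl("^>", lines)
  if (!hdr[1L] || !all(diff(which(hdr)) == 2L) || sum(!hdr) != sum(hdr)) {
    abort("malformed map file: expected alternating header and fragment lines")
  }
  purrr::map2(lines[hdr], lines[!hdr], function(h, f) {
    tok <- strsplit(trimws(sub("^>", "", h)), "\\s+")[[1L]]
    lens <- as.numeric(strsplit(trimws(f), "\\s+")[[1L]])
    optical_map(tok[1L], if (length(tok) > 1L) tok[2L] else NA_character_, lens)
  }) |>
    bind_rows()
}

#' @rdname map_io
#' @export
write_maps_tsv <- function(maps, path) {
  rows <- purrr::map(split_maps(maps), function(m) {
    tibble(
      map_id = m$map_id[1L],
      enzyme = m$enzyme[1L],
      fragments = paste(format_len(m$length), collapse = ","),
      colors = if (all(is.na(m$color))) NA_character_ else
        paste(m$color, collapse = ",")
    )
  }) |> bind_rows()
  if (all(is.na(rows$colors))) rows$colors <- NULL
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname map_io
#' @export
read_maps_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = "character")
  purrr::pmap(df, function(map_id, enzyme, fragments, colors = NA) {
    lens <- as.numeric(strsplit(fragments, ",")[[1L]])
    cols <- if (is.na(colors)) NA_integer_ else {
      cc <- strsplit(colors, ",")[[1L]]
      cc[cc == "NA"] <- NA
      as.integer(cc)
    }
    optical_map(map_id, enzyme, lens, cols)
  }) |>
    bind_rows()
}

# full precision but no scientific notation; fractional trailing zeros
# trimmed (integers must keep theirs)
format_len <- function(x) {
  out <- format(x, scientific = FALSE, trim = TRUE, digits = 15)
  dec <- grepl(".", out, fixed = TRUE)
  out[dec] <- sub("\\.?0+$", "", out[dec])
  out
}

#' Read and write colored-read tables
#'
#' The colored-read file is a headerless TSV with columns
#' `read_id`, `start_color`, `end_color`; uncolored reads are omitted.
#' The color-map file (produced by [adjust_colors()]) is a headerless TSV
#' `old` -> `new`, one mapping per line.
#'
#' @param reads Tibble with columns `read_id`, `start_color`, `end_color`.
#' @param color_map Tibble with columns `old`, `new`.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name colored_read_io
NULL

#' @rdname colored_read_io
#' @export
write_colored_reads <- function(reads, path) {
  reads <- reads[!is.na(reads$start_color) & !is.na(reads$end_color), ]
  write.table(
    reads[, c("read_id", "start_color", "end_color")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname colored_read_io
#' @export
read_colored_reads <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (file.size(path) == 0L) {
    return(tibble(read_id = character(), start_color = integer(),
                  end_color = integer()))
  }
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("read_id", "start_color", "end_color"),
                   colClasses = c("character", "integer", "integer"))
  as_tibble(df)
}

#' @rdname colored_read_io
#' @export
write_color_map <- function(color_map, path) {
  write.table(color_map[, c("old", "new")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname colored_read_io
#' @export
read_color_map <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, col.names = c("old", "new"),
                   colClasses = "integer")
  as_tibble(df)
}

#' Write sequences to FASTA
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(as_dna(seqs), path, width = 80L)
  invisible(path)
}

#' Read a FASTA file as a DNAStringSet
#' @param path FASTA path.
#' @return A `DNAStringSet` with headers trimmed to the first token.
#' @export
read_fasta <- function(path) as_dna(path)
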