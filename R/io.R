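#' Read a BED file
#'
#' Accepts 3- to 6-column tab-separated BED.  `track` and `browser` header
#' lines are skipped.  Coordinates stay 0-based half-open.  Malformed lines
#' raise a format error naming the offending line number.
#'
#' @param path path to a BED file.
#' @param expected_columns optionally require this many columns.
#' @return an [intervals()] data frame in file order.
#' @export
read_bed <- function(path, expected_columns = NULL) {
  assert_that(file.exists(path), sprintf("no such file: %s", path),
              "spikeshift_format_error")
  lines <- readLines(path)
  keep <- !grepl("^(track|browser)\\b", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(intervals(character(), numeric(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (!is.null(expected_columns)) {
    bad <- which(ncols != expected_columns)
    assert_that(length(bad) == 0,
                sprintf("line %d: expected %d columns, found %d",
                        lineno[bad[1]], expected_columns, ncols[bad[1]]),
                "spikeshift_format_error")
  }
  bad <- which(ncols < 3 | ncols > 6)
  assert_that(length(bad) == 0,
              sprintf("line %d: BED needs 3-6 columns, found %d",
                      lineno[bad[1]], ncols[bad[1]]),
              "spikeshift_format_error")
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  chrom <- get_col(1, NA_character_)
  start_chr <- get_col(2, NA_character_)
  end_chr <- get_col(3, NA_character_)
  start <- suppressWarnings(as.numeric(start_chr))
  end <- suppressWarnings(as.numeric(end_chr))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  assert_that(length(bad) == 0,
              sprintf("line %d: non-integer coordinates", lineno[bad[1]]),
              "spikeshift_format_error")
  bad <- which(start >= end)
  assert_that(length(bad) == 0,
              sprintf("line %d: start >= end", lineno[bad[1]]),
              "spikeshift_format_error")
  name <- get_col(4, NA_character_)
  score <- suppressWarnings(as.numeric(get_col(5, NA_character_)))
  strand <- get_col(6, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  intervals(chrom, start, end, name = name, score = score, strand = strand)
}

#' Write intervals as BED
#'
#' Emits 6 columns when any of name/score/strand carries information,
#' otherwise BED3.  Round-trips through [read_bed()] on
#' (chrom, start, end, strand).
#'
#' @param x an [intervals()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  bed6 <- any(!is.na(x$name)) || any(!is.na(x$score)) || any(x$strand != ".")
  if (bed6) {
    out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                      ifelse(is.na(x$name), ".", x$name),
                      ifelse(is.na(x$score), 0, x$score),
                      x$strand)
  } else {
    out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end))
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a chrom.sizes file
#'
#' Two tab-separated columns (chromosome, length).  Order is preserved;
#' duplicate names and non-positive lengths are format errors.
#'
#' @param path path to a chrom.sizes file.
#' @return a [genome_index()].
#' @export
read_chrom_sizes <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path),
              "spikeshift_format_error")
  df <- read.delim(path, header = FALSE, sep = "\t",
                   colClasses = c("character", "numeric"),
                   col.names = c("chrom", "length"))
  assert_that(!anyDuplicated(df$chrom),
              sprintf("duplicate chromosome name: %s",
                      df$chrom[duplicated(df$chrom)][1]),
              "spikeshift_format_error")
  assert_that(all(df$length > 0), "non-positive chromosome length",
              "spikeshift_format_error")
  genome_index(setNames(df$length, df$chrom))
}

#' @rdname read_chrom_sizes
#' @param genome a [genome_index()].
#' @export
write_chrom_sizes <- function(genome, path) {
  write.table(data.frame(names(genome), format_coord(unname(genome))),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample counts table
#'
#' Plain TSV with a header row of sample names and row identifiers in the
#' first column.  Rows whose identifier starts with `spike_prefix`
#' (e.g. `"ERCC-"`) are flagged as spike-in rows.
#'
#' @param path path to the TSV.
#' @param spike_prefix optional row-identifier prefix marking spike-in rows.
#' @return a `ss_count_matrix`: list with `counts` (matrix), `is_spike`
#'   (logical per row), `spike_prefix`.
#' @export
read_counts_table <- function(path, spike_prefix = NULL) {
  assert_that(file.exists(path), sprintf("no such file: %s", path),
              "spikeshift_format_error")
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", row.names = 1,
               check.names = FALSE),
    error = function(e) ss_abort(conditionMessage(e), "spikeshift_format_error")
  )
  m <- as.matrix(df)
  assert_that(is.numeric(m) && !anyNA(m),
              "counts table contains non-numeric or missing cells",
              "spikeshift_format_error")
  assert_that(all(m >= 0), "negative count value", "spikeshift_format_error")
  count_matrix(m, spike_prefix = spike_prefix)
}

#' @rdname read_counts_table
#' @param counts numeric matrix with unique row and column names.
#' @export
count_matrix <- function(counts, spike_prefix = NULL) {
  counts <- as.matrix(counts)
  assert_that(!is.null(rownames(counts)) && !anyDuplicated(rownames(counts)),
              "row identifiers must be unique", "spikeshift_format_error")
  assert_that(!is.null(colnames(counts)) && !anyDuplicated(colnames(counts)),
              "sample names must be unique", "spikeshift_format_error")
  assert_that(all(counts >= 0), "negative count value",
              "spikeshift_format_error")
  is_spike <- if (is.null(spike_prefix)) rep(FALSE, nrow(counts)) else
    startsWith(rownames(counts), spike_prefix)
  structure(list(counts = counts, is_spike = is_spike,
                 spike_prefix = spike_prefix),
            class = "ss_count_matrix")
}

#' @export
print.ss_count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d rows (%d spike) x %d samples\n",
              nrow(x$counts), sum(x$is_spike), ncol(x$counts)))
  invisible(x)
}

#' @rdname read_counts_table
#' @param x a `ss_count_matrix`.
#' @export
write_counts_table <- function(x, path) {
  out <- data.frame(id = rownames(x$counts), x$counts, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one sample of a bin matrix as bedGraph
#'
#' Four columns (chrom, start, end, value), 0-based half-open, one line per
#' bin, no header.  Values round-trip through [read_bedgraph()] to 6 decimal
#' places.
#'
#' @param bins a [bin_matrix()].
#' @param sample sample (column) name to export.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, sample, path) {
  assert_that(sample %in% colnames(bins$counts),
              sprintf("unknown sample: %s", sample),
              "spikeshift_lookup_error")
  if (nrow(bins$counts) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  out <- data.frame(bins$bins$chrom, format_coord(bins$bins$start),
                    format_coord(bins$bins$end),
                    sub("\\.?0+$", "", sprintf("%.6f", bins$counts[, sample])))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser)\\b", lines)]
  if (length(lines) == 0) {
    return(list(bins = intervals(character(), numeric(), numeric()),
                value = numeric()))
  }
  df <- read.delim(text = lines, header = FALSE, sep = "\t",
                   col.names = c("chrom", "start", "end", "value"))
  list(bins = intervals(df$chrom, df$start, df$end), value = df$value)
}

#' Read/write bin-count tables
#'
#' Bins x samples TSV with three leading coordinate columns
#' (`chrom`, `start`, `end`) followed by one column per sample.
#'
#' @param path path to the TSV.
#' @return a [bin_matrix()] (`read_bin_counts`); `path` invisibly
#'   (`write_bin_counts`).
#' @export
read_bin_counts <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path),
              "spikeshift_format_error")
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  assert_that(ncol(df) > 3, "bin counts need coordinate + sample columns",
              "spikeshift_format_error")
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  bin_matrix(intervals(df[[1]], df[[2]], df[[3]]), m)
}

#' @rdname read_bin_counts
#' @param bins a [bin_matrix()].
#' @export
write_bin_counts <- function(bins, path) {
  out <- data.frame(chrom = bins$bins$chrom,
                    start = format_coord(bins$bins$start),
                    end = format_coord(bins$bins$end),
                    bins$counts, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
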