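#' Read a BED3/BED6 file
#'
#' Coordinates are converted from BED's 0-based half-open convention to the
#' 1-based `GRanges` used throughout the package.  Lines that do not parse,
#' or whose coordinates violate `end > start >= 0`, raise an error naming the
#' offending line; nothing is silently clamped.
#'
#' @param path path to a tab-separated BED file (>= 3 columns; column 4 name,
#'   column 6 strand are kept when present).
#' @return `GRanges` in file order, with a `name` metadata column if present.
#' @export
read_bed <- function(path) {
  lines <- .read_data_lines(path)
  if (!length(lines$text))
    return(GenomicRanges::GRanges())
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3))
    stop(sprintf("%s: line %d has fewer than 3 columns",
                 path, lines$lineno[which(ncol < 3)[1]]))
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("%s: line %d has non-numeric coordinates",
                 path, lines$lineno[bad[1]]))
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop(sprintf("%s: line %d violates end > start >= 0",
                 path, lines$lineno[bad[1]]))
  strand <- ifelse(ncol >= 6, vapply(fields, function(f) f[min(6L, length(f))], ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- as_granges_bed(chrom, start, end, strand)
  if (any(ncol >= 4))
    S4Vectors::mcols(gr)$name <- ifelse(ncol >= 4,
      vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  gr
}

#' Read an ENCODE narrowPeak file
#'
#' Ten tab-separated columns; column 7 is `signalValue`, column 10 the summit
#' offset from the peak start (`-1` when absent).  The result carries
#' `signalValue` and `summit` (absolute 1-based position, `NA` when absent)
#' metadata columns.
#'
#' @param path path to a narrowPeak file.
#' @return `GRanges` with `name`, `score`, `signalValue`, `pValue`, `qValue`
#'   and `summit` metadata columns.
#' @export
read_narrowpeak <- function(path) {
  lines <- .read_data_lines(path)
  if (!length(lines$text))
    return(.empty_peaks())
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol != 10L))
    stop(sprintf("%s: line %d has %d columns, narrowPeak requires 10",
                 path, lines$lineno[which(ncol != 10L)[1]],
                 ncol[which(ncol != 10L)[1]]))
  m <- matrix(unlist(fields), ncol = 10L, byrow = TRUE)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop(sprintf("%s: line %d has non-numeric %s",
                   path, lines$lineno[which(is.na(v))[1]], what))
    v
  }
  start <- num(2, "start"); end <- num(3, "end")
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop(sprintf("%s: line %d violates end > start >= 0",
                 path, lines$lineno[bad[1]]))
  signal <- num(7, "signalValue")
  if (any(signal < 0))
    stop(sprintf("%s: negative signalValue at line %d",
                 path, lines$lineno[which(signal < 0)[1]]))
  summit_off <- num(10, "summit offset")
  strand <- m[, 6]; strand[!strand %in% c("+", "-")] <- "*"
  gr <- as_granges_bed(m[, 1], start, end, strand)
  summit <- ifelse(summit_off < 0, NA_real_, start + summit_off + 1)
  if (any(!is.na(summit) & (summit < GenomicRanges::start(gr) |
                            summit > GenomicRanges::end(gr))))
    stop(sprintf("%s: summit outside its peak at line %d", path,
                 lines$lineno[which(!is.na(summit) &
                   (summit < GenomicRanges::start(gr) |
                    summit > GenomicRanges::end(gr)))[1]]))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = m[, 4], score = num(5, "score"), signalValue = signal,
    pValue = num(8, "pValue"), qValue = num(9, "qValue"), summit = summit)
  gr
}

.empty_peaks <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(0), score = numeric(0), signalValue = numeric(0),
    pValue = numeric(0), qValue = numeric(0), summit = numeric(0))
  gr
}

# skip blank lines and track/browser/comment headers, keep line numbers
.read_data_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  txt <- readLines(path, warn = FALSE)
  keep <- nzchar(txt) & !grepl("^(track|browser|#)", txt)
  list(text = txt[keep], lineno = which(keep))
}

#' Write a signal track as bedGraph
#'
#' Steps are written one per line in `chrom start end value` form (0-based
#' half-open), values at 6 significant digits so that write-then-read
#' round-trips.  Within each chromosome, steps must be sorted and
#' non-overlapping.
#'
#' @param track `GRanges` with a numeric `score` metadata column.
#' @param path output path.
#' @param natural_sort sort chromosomes naturally (`chr2` before `chr10`)
#'   before writing; if `FALSE` the track's existing chromosome order is
#'   required to be unique-blocked.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, natural_sort = TRUE) {
  stopifnot(is(track, "GRanges"))
  if (is.null(track$score)) stop("track needs a 'score' metadata column")
  if (length(track)) {
    chrom <- as.character(GenomicRanges::seqnames(track))
    if (natural_sort) {
      key <- order(.natural_key(chrom), GenomicRanges::start(track))
      track <- track[key]
      chrom <- chrom[key]
    } else if (anyDuplicated(rle(chrom)$values)) {
      stop("chromosome blocks not contiguous; set natural_sort = TRUE")
    }
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      s <- GenomicRanges::start(track)[idx]; e <- GenomicRanges::end(track)[idx]
      if (is.unsorted(s) || any(s[-1] <= e[-length(e)]))
        stop(sprintf("overlapping or unsorted steps on %s", ch))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(track)) {
    writeLines(sprintf("%s\t%d\t%d\t%s",
                       as.character(GenomicRanges::seqnames(track)),
                       GenomicRanges::start(track) - 1L,
                       GenomicRanges::end(track),
                       formatC(track$score, digits = 6, format = "g")),
               con)
  }
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path path to a 4-column bedGraph file.
#' @return `GRanges` with a `score` metadata column, in file order.
#' @export
read_bedgraph <- function(path) {
  lines <- .read_data_lines(path)
  if (!length(lines$text)) {
    gr <- GenomicRanges::GRanges()
    gr$score <- numeric(0)
    return(gr)
  }
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L))
    stop(sprintf("%s: line %d is not 4-column bedGraph",
                 path, lines$lineno[which(lengths(fields) != 4L)[1]]))
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  val <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(val))
  if (length(bad))
    stop(sprintf("%s: line %d has non-numeric fields", path, lines$lineno[bad[1]]))
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop(sprintf("%s: line %d violates end > start >= 0", path, lines$lineno[bad[1]]))
  gr <- as_granges_bed(m[, 1], start, end)
  gr$score <- val
  gr
}

.natural_key <- function(chrom) {
  num <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
  num[is.na(num)] <- 1000L + as.integer(factor(chrom[is.na(num)]))
  num
}

#' Write / read a dense contact matrix as TSV
#'
#' Square matrices are stored with bin-start coordinates as row and column
#' headers so that a round trip preserves both values (6 significant digits)
#' and bin addressing.
#'
#' @param mat a `contact_matrix` (see [contact_matrix()]).
#' @param path file path.
#' @return `write_contact_matrix` returns `path` invisibly;
#'   `read_contact_matrix` returns a `contact_matrix`.
#' @export
write_contact_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "contact_matrix"))
  bins <- mat$start + (seq_len(nrow(mat$matrix)) - 1L) * mat$resolution
  m <- format(mat$matrix, digits = 6, trim = TRUE, scientific = FALSE)
  hdr <- paste(c(sprintf("#chrom=%s;resolution=%d;start=%d;kind=%s",
                         mat$chrom, mat$resolution, mat$start, mat$kind)),
               collapse = "")
  body <- c(paste(c("bin", bins), collapse = "\t"),
            vapply(seq_len(nrow(m)), function(i)
              paste(c(bins[i], m[i, ]), collapse = "\t"), ""))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  txt <- readLines(path, warn = FALSE)
  meta <- sub("^#", "", txt[1])
  kv <- strsplit(strsplit(meta, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  body <- strsplit(txt[-(1:2)], "\t", fixed = TRUE)
  vals <- t(vapply(body, function(f) as.numeric(f[-1]),
                   numeric(length(body[[1]]) - 1L)))
  contact_matrix(vals, resolution = as.integer(meta[["resolution"]]),
                 chrom = meta[["chrom"]], start = as.integer(meta[["start"]]),
                 kind = meta[["kind"]])
}
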