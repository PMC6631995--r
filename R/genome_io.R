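# Readers/writers for the plain-text formats the pipeline touches, plus
# sequence statistics. Coordinate conventions are fixed package-wide:
# all internal coordinates are 0-based half-open; VCF is the only 1-based
# surface. Repeat masking is carried exclusively by lowercase.

GENOME_ALPHABET <- c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")

#' Construct a validated genome object
#'
#' A genome is a named character vector of nucleotide strings over
#' `A,C,G,T,N` in either case; lowercase marks repeat-masked bases.
#'
#' @param records named character vector of sequences.
#' @return the validated named character vector, classed `"genome"`.
#' @export
genome <- function(records) {
  if (is.null(names(records)) || any(names(records) == ""))
    stop_fmt("genome records must be named")
  if (anyDuplicated(names(records)))
    stop_fmt("duplicate record name: %s",
             names(records)[anyDuplicated(names(records))])
  if (any(nchar(records) == 0L))
    stop_fmt("zero-length record: %s", names(records)[nchar(records) == 0L][1])
  for (nm in names(records)) {
    bad <- stringi::stri_locate_first_regex(records[[nm]], "[^ACGTNacgtn]")[1, 1]
    if (!is.na(bad))
      stop_fmt("record '%s' has non-alphabet character at position %d", nm, bad)
  }
  structure(records, class = "genome")
}

#' Read a FASTA file into a genome
#'
#' Case is preserved exactly (it carries the repeat mask) and record order is
#' kept. Duplicate record names and non-nucleotide characters are hard errors.
#'
#' @param path FASTA file, optionally gzip-compressed.
#' @return a [genome()] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  x <- Biostrings::readBStringSet(path)
  recs <- as.character(x)
  names(recs) <- sub("\\s.*$", "", names(x))
  genome(recs)
}

#' Write a genome to FASTA
#'
#' @param g a [genome()] object.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(g, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(unclass(g)), path,
                              width = width)
  invisible(path)
}

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open. `strand` is `"+"`, `"-"` or `"."`.
#'
#' @param chrom,start,end,strand,id vectors, recycled to common length.
#' @return a `data.frame` with columns chrom, start, end, strand, id.
#' @export
gintervals <- function(chrom, start, end, strand = ".", id = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   id = as.character(id), stringsAsFactors = FALSE)
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad))
    stop_fmt("invalid interval at row %d: [%d, %d)", bad[1],
             df$start[bad[1]], df$end[bad[1]])
  df
}

#' Read a BED3/BED6 file
#'
#' BED semantics: 0-based half-open; optional column 4 is an id, column 6 a
#' strand. Lines with `end <= start` raise an error naming the line.
#'
#' @param path BED file (plain or gzipped).
#' @return interval `data.frame` as from [gintervals()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (!length(lines)) return(gintervals(character(), integer(), integer())[0, ])
  parts <- stringi::stri_split_fixed(lines, "\t")
  ncol1 <- lengths(parts)
  if (any(ncol1 < 3L))
    stop_fmt("BED line %d has fewer than 3 columns", which(ncol1 < 3L)[1])
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop_fmt("BED line %d has non-integer coordinates",
             which(is.na(start) | is.na(end))[1])
  bad <- which(end <= start)
  if (length(bad))
    stop_fmt("BED line %d: end (%d) <= start (%d)", bad[1], end[bad[1]],
             start[bad[1]])
  id <- ifelse(ncol1 >= 4L, vapply(parts, function(p)
    if (length(p) >= 4L) p[[4L]] else NA_character_, ""), NA_character_)
  strand <- ifelse(ncol1 >= 6L, vapply(parts, function(p)
    if (length(p) >= 6L) p[[6L]] else ".", ""), ".")
  strand[!strand %in% c("+", "-")] <- "."
  gintervals(chrom, start, end, strand, id)
}

#' Write intervals to BED
#'
#' Emits BED6 when any id or strand is set, BED3 otherwise. Extra columns
#' named in `extra` are appended after the six standard ones.
#'
#' @param ivs interval `data.frame`.
#' @param path output path.
#' @param extra character vector of extra column names in `ivs` to append.
#' @export
write_bed <- function(ivs, path, extra = character()) {
  has6 <- any(!is.na(ivs$id)) || any(ivs$strand %in% c("+", "-")) ||
    length(extra) > 0
  if (has6) {
    out <- data.frame(ivs$chrom, ivs$start, ivs$end,
                      ifelse(is.na(ivs$id), ".", ivs$id), 0L,
                      ivs$strand, stringsAsFactors = FALSE)
    for (cn in extra) out[[cn]] <- ivs[[cn]]
  } else {
    out <- ivs[, c("chrom", "start", "end")]
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a signal track
#'
#' A signal track is a set of non-overlapping intervals with non-negative
#' coverage values, e.g. binned ChIP-seq or DNase coverage.
#'
#' @param name signal identifier (e.g. a histone mark).
#' @param bins `data.frame` with columns chrom, start, end, value.
#' @return an object of class `"signal_track"`.
#' @export
signal_track <- function(name, bins) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(bins)))
  if (any(bins$value < 0)) stop_fmt("track '%s' has negative coverage", name)
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
  sp <- split(seq_len(nrow(bins)), bins$chrom)
  for (idx in sp) {
    if (length(idx) > 1L &&
        any(bins$start[idx][-1] < bins$end[idx][-length(idx)]))
      stop_fmt("track '%s' has overlapping intervals on %s", name,
               bins$chrom[idx[1]])
  }
  rownames(bins) <- NULL
  structure(list(name = name, bins = bins), class = "signal_track")
}

#' Read a bedGraph file into a signal track
#'
#' Intervals are sorted; adjacent intervals with equal values are coalesced.
#' Negative values and overlapping intervals are errors.
#'
#' @param path bedGraph file.
#' @param name track name (defaults to the file stem).
#' @return a [signal_track()].
#' @export
read_bedgraph <- function(path, name = NULL) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  name <- name %||% sub("\\.(bedgraph|bg)(\\.gz)?$", "",
                        basename(path), ignore.case = TRUE)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = list(character = 1))
  if (any(dt$value < 0)) stop_fmt("negative value in %s", path)
  df <- as.data.frame(dt)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  # coalesce adjacent equal-valued intervals per chromosome
  keep <- !(c(FALSE, df$chrom[-1] == df$chrom[-nrow(df)] &
                df$start[-1] == df$end[-nrow(df)] &
                df$value[-1] == df$value[-nrow(df)]))
  grp <- cumsum(keep)
  df2 <- data.frame(
    chrom = df$chrom[keep],
    start = df$start[keep],
    end = tapply(df$end, grp, max)[as.character(seq_len(sum(keep)))],
    value = df$value[keep], stringsAsFactors = FALSE)
  df2$end <- as.integer(df2$end)
  signal_track(name, df2)
}

#' Write a signal track to bedGraph
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  data.table::fwrite(track$bins, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read single-nucleotide variants from a minimal VCF
#'
#' Only CHROM/POS/REF/ALT are consumed; header lines are ignored. POS is
#' converted from 1-based to the package's 0-based convention, multiallelic
#' ALT fields are split into one record per allele, and indels are rejected.
#' When a genome is supplied, REF is checked against it (case-insensitively).
#'
#' @param path VCF file.
#' @param genome optional [genome()] for REF validation.
#' @return `data.frame` with columns chrom, pos (0-based), ref, alt.
#' @export
read_vcf_lite <- function(path, genome = NULL) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  parts <- stringi::stri_split_fixed(lines, "\t")
  if (any(lengths(parts) < 5L))
    stop_fmt("VCF line %d has fewer than 5 columns", which(lengths(parts) < 5L)[1])
  chrom <- vapply(parts, `[[`, "", 1L)
  pos1 <- as.integer(vapply(parts, `[[`, "", 2L))
  ref <- toupper(vapply(parts, `[[`, "", 4L))
  alts <- stringi::stri_split_fixed(toupper(vapply(parts, `[[`, "", 5L)), ",")
  n_alt <- lengths(alts)
  out <- data.frame(
    chrom = rep(chrom, n_alt), pos = rep(pos1, n_alt) - 1L,
    ref = rep(ref, n_alt), alt = unlist(alts), stringsAsFactors = FALSE)
  bad <- which(nchar(out$ref) != 1L | nchar(out$alt) != 1L)
  if (length(bad))
    stop_fmt("indel records are not supported (%s:%d %s>%s)",
             out$chrom[bad[1]], out$pos[bad[1]] + 1L, out$ref[bad[1]],
             out$alt[bad[1]])
  bad <- which(out$ref == out$alt)
  if (length(bad))
    stop_fmt("REF equals ALT at %s:%d", out$chrom[bad[1]], out$pos[bad[1]] + 1L)
  if (!is.null(genome)) {
    gb <- toupper(substring(genome[out$chrom], out$pos + 1L, out$pos + 1L))
    bad <- which(gb != out$ref)
    if (length(bad))
      stop_fmt("REF mismatch at %s:%d: VCF says %s, genome has %s",
               out$chrom[bad[1]], out$pos[bad[1]] + 1L, out$ref[bad[1]],
               gb[bad[1]])
  }
  rownames(out) <- NULL
  out
}

#' Write variants to a minimal VCF
#'
#' @param variants `data.frame` with chrom, pos (0-based), ref, alt.
#' @param path output path.
#' @export
write_vcf_lite <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", variants$chrom,
                       variants$pos + 1L, variants$ref, variants$alt), con)
  invisible(path)
}

#' GC and repeat content of a sequence
#'
#' GC is computed case-insensitively with `N` excluded from the denominator;
#' repeat content is the fraction of lowercase (repeat-masked) bases.
#'
#' @param seq a nucleotide string.
#' @return list with elements `gc` (NA with a warning if no non-N bases) and
#'   `repeat_frac`.
#' @export
seq_stats <- function(seq) {
  stopifnot(length(seq) == 1L, nchar(seq) > 0L)
  n <- nchar(seq)
  counts <- stringi::stri_count_fixed(seq,
    c("A", "a", "C", "c", "G", "g", "T", "t"))
  acgt <- sum(counts)
  gc <- if (acgt == 0L) {
    warn_fmt("all-N sequence: GC content undefined")
    NA_real_
  } else sum(counts[3:6]) / acgt
  rep_frac <- stringi::stri_count_regex(seq, "[acgtn]") / n
  list(gc = gc, repeat_frac = rep_frac)
}

#' Extract the sequence of an interval from a genome
#'
#' Minus-strand intervals return the reverse complement of the plus-strand
#' sequence; case travels with its base.
#'
#' @param genome a [genome()].
#' @param chrom,start,end 0-based half-open coordinates.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return a nucleotide string of length `end - start`.
#' @export
extract_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop_fmt("unknown chromosome: %s", chrom)
  L <- nchar(genome[[chrom]])
  if (start < 0L || end > L || start >= end)
    stop_fmt("interval [%d, %d) out of bounds for %s (length %d)",
             start, end, chrom, L)
  s <- substring(genome[[chrom]], start + 1L, end)
  if (identical(strand, "-")) revcomp(s) else s
}
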