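#' Read genomic intervals from a BED-family file
#'
#' Understands plain 3-column BED, 5+-column scored BED and the narrowPeak
#' dialect (10 columns; column 10 is the summit offset relative to `start`,
#' -1 meaning absent). Coordinates are taken as written: BED is 0-based
#' half-open, which is also the package's internal convention.
#'
#' @param path Path to a tab-separated BED-like file.
#' @param genome A [genome_model()]; every record must lie on one of its
#'   chromosomes.
#' @return A peak tibble with columns `chrom`, `start`, `end`, `score`
#'   (column 5 when present, otherwise 0), and `summit` (absolute bp position
#'   from a narrowPeak 10th column, otherwise `NA`), sorted by genome
#'   chromosome order then start.
#' @export
read_intervals <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(peak_tbl(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      score = numeric(), summit = numeric())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop("malformed BED line ", which(ncol < 3)[1], ": fewer than 3 columns",
         call. = FALSE)
  }
  get_col <- function(j) vapply(fields, function(f) {
    if (length(f) >= j) f[[j]] else NA_character_
  }, character(1))
  start <- suppressWarnings(as.numeric(get_col(2)))
  end <- suppressWarnings(as.numeric(get_col(3)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad)) {
    stop("malformed BED line ", bad[1], ": coordinates do not parse",
         call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = get_col(1),
    start = start,
    end = end,
    score = {
      s <- suppressWarnings(as.numeric(get_col(5)))
      ifelse(is.finite(s), s, 0)
    },
    summit = {
      if (all(ncol >= 10)) {
        off <- suppressWarnings(as.numeric(get_col(10)))
        ifelse(is.finite(off) & off >= 0, start + off, NA_real_)
      } else {
        NA_real_
      }
    }
  )
  check_intervals(out, genome, "BED record")
  peak_tbl(sort_genomic(out, genome))
}

peak_tbl <- function(x) {
  if (!"score" %in% names(x)) x$score <- 0
  class(x) <- unique(c("peak_set", class(x)))
  x
}

#' Write intervals to a BED file
#'
#' Emits tab-separated, newline-terminated records: `chrom start end name
#' score` (name is a running id). Value-identical under a
#' [read_intervals()] round-trip.
#'
#' @param x A peak tibble (`chrom`, `start`, `end`, optional `score`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  score <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), paste0("region_", seq_len(nrow(x))),
                   format(score, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fixed-bin signal track from a bedGraph file
#'
#' Records are length-weighted averaged into fixed bins of `bin_size`;
#' uncovered bp contribute value 0 to their bin, so a bin half covered by
#' value 4 reads 2. Records must not overlap.
#'
#' @param path bedGraph file (`chrom start end value`, tab-separated).
#' @param genome A [genome_model()].
#' @param bin_size Bin width in bp.
#' @return A `signal_track` tibble: columns `chrom`, `bin` (0-based index),
#'   `start`, `value`, dense over every bin of every genome chromosome, with
#'   attributes `bin_size` and `normalization`.
#' @export
read_track <- function(path, genome, bin_size) {
  if (length(bin_size) != 1 || !is.finite(bin_size) || bin_size <= 0) {
    stop("`bin_size` must be a single positive number", call. = FALSE)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"),
                          col.names = c("chrom", "start", "end", "value"))
  df <- tibble::as_tibble(df)
  check_intervals(df, genome, "bedGraph record")
  df <- sort_genomic(df, genome)
  ov <- dplyr::group_by(df, .data$chrom)
  ov <- dplyr::summarise(ov,
    overlap = any(.data$start[-1] < .data$end[-length(.data$end)]))
  if (any(ov$overlap, na.rm = TRUE)) {
    stop("overlapping bedGraph records on ",
         paste(ov$chrom[which(ov$overlap)], collapse = ", "), call. = FALSE)
  }
  track <- empty_track(genome, bin_size)
  if (nrow(df) > 0) {
    # distribute each record's value into bins, weighted by covered length
    pieces <- purrr::pmap_dfr(
      list(df$chrom, df$start, df$end, df$value),
      function(chrom, start, end, value) {
        b0 <- floor(start / bin_size)
        b1 <- floor((end - 1) / bin_size)
        bins <- b0:b1
        lo <- pmax(start, bins * bin_size)
        hi <- pmin(end, (bins + 1) * bin_size)
        tibble::tibble(chrom = chrom, bin = bins,
                       mass = value * (hi - lo))
      })
    mass <- dplyr::summarise(dplyr::group_by(pieces, .data$chrom, .data$bin),
                             mass = sum(.data$mass), .groups = "drop")
    idx <- match(paste(mass$chrom, mass$bin),
                 paste(track$chrom, track$bin))
    # last bin of a chromosome may be short; divide by its true width
    width <- pmin((track$bin[idx] + 1) * bin_size,
                  genome_size(genome, track$chrom[idx])) - track$start[idx]
    track$value[idx] <- mass$mass / width
  }
  track
}

empty_track <- function(genome, bin_size, normalization = "raw") {
  nb <- genome_nbins(genome, genome$chrom, bin_size)
  out <- tibble::tibble(
    chrom = rep(genome$chrom, nb),
    bin = unlist(lapply(nb, function(n) seq_len(n) - 1L), use.names = FALSE)
  )
  out$start <- out$bin * bin_size
  out$value <- 0
  new_signal_track(out, bin_size, normalization)
}

new_signal_track <- function(x, bin_size, normalization = "raw") {
  attr(x, "bin_size") <- bin_size
  attr(x, "normalization") <- normalization
  class(x) <- unique(c("signal_track", class(x)))
  x
}

track_bin_size <- function(track) attr(track, "bin_size")

#' Write a signal track to a bedGraph file
#'
#' One record per bin (zero-valued bins included so round-trips are
#' value-identical); tab-separated, newline-terminated.
#'
#' @param track A `signal_track` tibble from [read_track()] or the
#'   simulators.
#' @param path Output file path.
#' @param genome Optional [genome_model()] used to clip the final bin's end.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, genome = NULL) {
  bs <- track_bin_size(track)
  end <- track$start + bs
  if (!is.null(genome)) end <- pmin(end, genome_size(genome, track$chrom))
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                   as.integer(end),
                   format(track$value, trim = TRUE, scientific = FALSE,
                          digits = 15))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene table
#'
#' Tab-separated with header `id chrom strand tss tes`. The TSS/TES carry
#' the orientation: for a `-` strand gene the TSS is the larger coordinate.
#'
#' @param path Path to the gene table.
#' @param genome A [genome_model()].
#' @return A tibble `id, chrom, strand, tss, tes` sorted by genome order
#'   then TSS.
#' @export
read_genes <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("id", "chrom", "strand", "tss", "tes")
  if (!all(need %in% names(df))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df[need])
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  if (any(df$tss == df$tes)) stop("gene tss must differ from tes", call. = FALSE)
  ok_orient <- ifelse(df$strand == "+", df$tss < df$tes, df$tss > df$tes)
  if (!all(ok_orient)) {
    stop("gene orientation inconsistent with strand for: ",
         paste(utils::head(df$id[!ok_orient], 3), collapse = ", "),
         call. = FALSE)
  }
  key <- match(df$chrom, genome$chrom)
  if (anyNA(key)) {
    stop("gene chromosome(s) not in genome: ",
         paste(unique(df$chrom[is.na(key)]), collapse = ", "), call. = FALSE)
  }
  df[order(key, df$tss), ]
}

#' Write a gene table
#' @param genes A gene tibble (`id`, `chrom`, `strand`, `tss`, `tes`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes[c("id", "chrom", "strand", "tss", "tes")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read loops from a BEDPE-style file
#'
#' Six or more tab-separated columns:
#' `chrom1 start1 end1 chrom2 start2 end2 [score ...]`. Only
#' intrachromosomal loops are meaningful to the package; interchromosomal
#' records are dropped with a message. Anchors are normalised so anchor 1 is
#' upstream.
#'
#' @param path BEDPE file path.
#' @param genome A [genome_model()].
#' @param resolution Anchor resolution in bp recorded on the result.
#' @return A loop tibble: `chrom`, `start1`, `end1`, `start2`, `end2`,
#'   `score`, `resolution`, plus `length` (anchor midpoint separation).
#' @export
read_loops <- function(path, genome, resolution = NA_real_) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && any(lengths(fields) < 6)) {
    stop("malformed BEDPE line ", which(lengths(fields) < 6)[1], call. = FALSE)
  }
  col <- function(j) vapply(fields, `[[`, character(1), j)
  num <- function(j) as.numeric(col(j))
  df <- tibble::tibble(
    chrom1 = if (length(fields)) col(1) else character(),
    start1 = if (length(fields)) num(2) else numeric(),
    end1 = if (length(fields)) num(3) else numeric(),
    chrom2 = if (length(fields)) col(4) else character(),
    start2 = if (length(fields)) num(5) else numeric(),
    end2 = if (length(fields)) num(6) else numeric(),
    score = if (length(fields) && all(lengths(fields) >= 7)) {
      s <- suppressWarnings(num(7)); ifelse(is.finite(s), s, NA_real_)
    } else NA_real_
  )
  n_trans <- sum(df$chrom1 != df$chrom2)
  if (n_trans > 0) {
    message("dropped ", n_trans, " interchromosomal loop(s)")
    df <- df[df$chrom1 == df$chrom2, ]
  }
  loop_tbl(df$chrom1, df$start1, df$end1, df$start2, df$end2,
           score = df$score, resolution = resolution, genome = genome)
}

#' Construct a loop tibble
#'
#' @param chrom,start1,end1,start2,end2 Anchor coordinates (same chromosome;
#'   anchors are swapped if given out of order).
#' @param score Optional per-loop score.
#' @param resolution Anchor resolution in bp.
#' @param genome Optional [genome_model()] for validation and sorting.
#' @return A loop tibble with a `length` column (midpoint separation in bp).
#' @export
loop_tbl <- function(chrom, start1, end1, start2, end2, score = NA_real_,
                     resolution = NA_real_, genome = NULL) {
  swap <- start1 > start2 | (start1 == start2 & end1 > end2)
  s1 <- ifelse(swap, start2, start1)
  e1 <- ifelse(swap, end2, end1)
  s2 <- ifelse(swap, start1, start2)
  e2 <- ifelse(swap, end1, end2)
  out <- tibble::tibble(
    chrom = as.character(chrom),
    start1 = s1, end1 = e1, start2 = s2, end2 = e2,
    score = score,
    resolution = resolution
  )
  out$length <- interval_mid(out$start2, out$end2) -
    interval_mid(out$start1, out$end1)
  if (nrow(out) && any(out$length <= 0)) {
    stop("loop anchors must be distinct (length > 0)", call. = FALSE)
  }
  if (!is.null(genome)) {
    check_intervals(tibble::tibble(chrom = out$chrom, start = out$start1,
                                   end = out$end1), genome, "loop anchor")
    check_intervals(tibble::tibble(chrom = out$chrom, start = out$start2,
                                   end = out$end2), genome, "loop anchor")
    key <- match(out$chrom, genome$chrom)
    out <- out[order(key, out$start1, out$start2), ]
  }
  out
}

#' Write loops to a BEDPE file
#' @param loops A loop tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path) {
  score <- if ("score" %in% names(loops)) loops$score else NA_real_
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s",
                   loops$chrom, as.integer(loops$start1),
                   as.integer(loops$end1), loops$chrom,
                   as.integer(loops$start2), as.integer(loops$end2),
                   ifelse(is.na(score), ".",
                          format(score, trim = TRUE, scientific = FALSE)))
  writeLines(lines, path)
  invisible(path)
}
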