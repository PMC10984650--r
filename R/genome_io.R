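# Reading and normalising genomic inputs: feature tracks (BED), recombination
# maps, allele-count tables; building the segment and window structures the
# theory operates on.  All coordinates are 0-based half-open internally (BED
# convention); strand is ignored throughout.

.track_granges <- function(chrom, start, end, class_label) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start + 1L, end = end))
  S4Vectors::mcols(gr)$class_label <- class_label
  gr
}

.gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Build a feature track from interval vectors
#'
#' Intervals are sorted and merged within the class so the track invariants
#' (sorted, non-overlapping, `start < end`) hold by construction.
#'
#' @param chrom,start,end interval vectors, 0-based half-open.
#' @param class_label single feature class name (e.g. `"cds"`,
#'   `"phastcons"`).
#' @return a `GRanges` with a `class_label` metadata column (a feature track).
#' @export
feature_track <- function(chrom, start, end, class_label) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(end <= start)) stop("feature_track: intervals need start < end")
  raw <- GenomeInfoDb::sortSeqlevels(.track_granges(chrom, start, end,
                                                    class_label))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(raw))
  S4Vectors::mcols(gr)$class_label <- class_label
  gr
}

#' Read a BED file into a feature track
#'
#' Reads the first three columns of a BED (0-based half-open) file, rejects
#' malformed records (`end <= start`) with a message, normalises chromosome
#' names to character, and merges overlapping records within the class (with
#' a warning, since a clean track should not contain overlaps).
#'
#' @param path BED file (3+ columns, no header; `track`/`browser`/`#` lines
#'   are skipped).
#' @param class_label feature class to assign to every interval.
#' @return a feature-track `GRanges`; empty file gives an empty track.
#' @export
read_features <- function(path, class_label) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$class_label <- character(0)
    return(gr)
  }
  fields <- strsplit(lines, "\t| +")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | end <= start
  if (any(bad)) {
    message(sum(bad), " malformed BED record(s) rejected in ", path)
    chrom <- chrom[!bad]; start <- start[!bad]; end <- end[!bad]
  }
  if (length(chrom) == 0) return(feature_track(character(0), integer(0),
                                               integer(0), class_label))
  raw <- GenomeInfoDb::sortSeqlevels(.track_granges(chrom, start, end,
                                                    class_label))
  merged <- GenomicRanges::reduce(GenomicRanges::sort(raw))
  if (length(merged) < length(raw))
    warning("overlapping records merged within class '", class_label, "'")
  S4Vectors::mcols(merged)$class_label <- class_label
  merged
}

#' Resolve overlapping tracks into disjoint single-class segments
#'
#' Every basepair is assigned to exactly one feature class: the
#' highest-priority class whose track covers it (e.g. a PhastCons-priority
#' model classifies coding basepairs inside PhastCons elements as PhastCons).
#' Contiguous same-class runs become segments. With `chrom_lengths` given,
#' the remainder of each chromosome is assigned to `other_class` (the
#' full-track model); otherwise only annotated basepairs become segments.
#'
#' @param tracks list of feature-track GRanges (see [feature_track()]).
#' @param priority character vector ordering every class label present,
#'   highest priority first.
#' @param chrom_lengths optional named vector of chromosome lengths (bp);
#'   triggers the full-track model.
#' @param other_class class name for unannotated sequence.
#' @return a `bgs_segments` data frame with columns `chrom`, `start`, `end`,
#'   `class`, `L` (disjoint genome-wide, sorted).
#' @export
assign_priority <- function(tracks, priority, chrom_lengths = NULL,
                            other_class = "other") {
  labels <- vapply(tracks, function(t) S4Vectors::mcols(t)$class_label[1] %||%
                     NA_character_, "")
  labels[is.na(labels)] <- vapply(tracks[is.na(labels)], function(t) "empty", "")
  have <- unique(labels[!is.na(labels)])
  if (!all(have %in% priority))
    stop("priority list is missing class(es): ",
         paste(setdiff(have, priority), collapse = ", "))
  if (!all(priority %in% c(have, other_class)))
    stop("unknown class in priority list: ",
         paste(setdiff(priority, c(have, other_class)), collapse = ", "))
  claimed <- GenomicRanges::GRanges()
  out <- list()
  for (cls in priority) {
    idx <- which(labels == cls)
    if (length(idx) == 0) next
    gr <- GenomicRanges::reduce(do.call(c, lapply(tracks[idx], function(g) {
      GenomicRanges::granges(g)
    })))
    free <- GenomicRanges::setdiff(gr, claimed)
    claimed <- GenomicRanges::reduce(c(claimed, free))
    if (length(free)) {
      df <- .gr_to_df(free)
      df$class <- cls
      out[[cls]] <- df
    }
  }
  if (!is.null(chrom_lengths)) {
    genome <- .track_granges(names(chrom_lengths), rep(0, length(chrom_lengths)),
                             as.numeric(chrom_lengths), other_class)
    rest <- GenomicRanges::setdiff(genome, claimed)
    if (length(rest)) {
      df <- .gr_to_df(rest)
      df$class <- other_class
      out[[other_class]] <- df
    }
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  seg$L <- seg$end - seg$start
  class(seg) <- c("bgs_segments", "data.frame")
  seg
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Read a recombination map
#'
#' Two dialects: `"hapmap"` — tab-separated `(chrom, pos, rate cM/Mb,
#' cumulative cM)` with a header line; `"cumulative"` — `(chrom, pos,
#' cumulative cM)`. Positions must be strictly increasing and the cumulative
#' map non-decreasing within each chromosome.
#'
#' @param path file path.
#' @param dialect map format.
#' @param header whether the file carries a header line.
#' @return a `bgs_recmap`: named list of per-chromosome data frames with
#'   `pos` (bp) and `cum` (Morgans).
#' @export
read_recmap <- function(path, dialect = c("hapmap", "cumulative"),
                        header = TRUE) {
  dialect <- match.arg(dialect)
  tab <- read.table(path, header = header, sep = "\t",
                    stringsAsFactors = FALSE)
  if (dialect == "hapmap") {
    stopifnot(ncol(tab) >= 4)
    df <- data.frame(chrom = as.character(tab[[1]]), pos = tab[[2]],
                     cum = tab[[4]] / 100)
  } else {
    stopifnot(ncol(tab) >= 3)
    df <- data.frame(chrom = as.character(tab[[1]]), pos = tab[[2]],
                     cum = tab[[3]] / 100)
  }
  recomb_map(df)
}

#' Build a recombination map from a (chrom, pos, cum) table
#'
#' @param df data frame with columns `chrom`, `pos` (bp) and `cum`
#'   (cumulative map position in Morgans).
#' @return a `bgs_recmap` object.
#' @export
recomb_map <- function(df) {
  stopifnot(all(c("chrom", "pos", "cum") %in% names(df)))
  sp <- split(df[c("pos", "cum")], df$chrom)
  sp <- lapply(sp, function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    if (any(diff(d$pos) <= 0)) stop("recomb_map: positions must be strictly increasing")
    if (any(diff(d$cum) < 0)) stop("recomb_map: cumulative map must be non-decreasing")
    rownames(d) <- NULL
    d
  })
  structure(sp, class = "bgs_recmap")
}

#' Uniform-rate recombination map
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param rate_cM_Mb constant rate in cM/Mb.
#' @return a `bgs_recmap`.
#' @export
uniform_recmap <- function(chrom_lengths, rate_cM_Mb = 1) {
  df <- data.frame(
    chrom = rep(names(chrom_lengths), each = 2),
    pos = as.numeric(rbind(0, chrom_lengths)),
    cum = as.numeric(rbind(0, chrom_lengths * rate_cM_Mb * 1e-8)))
  recomb_map(df)
}

#' Cumulative map position (Morgans) at basepair coordinates
#'
#' Linear interpolation between knots; positions outside the map extent are
#' clamped to the nearest knot with a warning.
#'
#' @param recmap a `bgs_recmap`.
#' @param chrom chromosome name (scalar).
#' @param pos basepair positions.
#' @return cumulative map positions in Morgans.
#' @export
map_position <- function(recmap, chrom, pos) {
  d <- recmap[[chrom]]
  if (is.null(d))
    stop("chromosome missing from recombination map: ", chrom)
  if (any(pos < d$pos[1] | pos > d$pos[nrow(d)]))
    warning("positions outside map extent on ", chrom,
            " clamped to nearest knot")
  approx(d$pos, d$cum, xout = pos, rule = 2, ties = "ordered")$y
}

#' Annotate segments with genetic-map quantities
#'
#' Adds the internal map length `M` (Morgans, cumulative map at `end` minus
#' at `start`) and the map coordinate of the segment midpoint (`map_mid`,
#' used for recombination-fraction queries). Segments whose internal map
#' length exceeds `split_M` are first split into equal-bp chunks so the
#' single-recombination-fraction approximation used by the reduction maps
#' stays accurate.
#'
#' @param segments a `bgs_segments` data frame.
#' @param recmap a `bgs_recmap`.
#' @param split_M maximum internal map length per segment (Morgans).
#' @return the annotated (possibly split) `bgs_segments`.
#' @export
annotate_map <- function(segments, recmap, split_M = 1e-3) {
  stopifnot(inherits(segments, "bgs_segments"))
  if (nrow(segments) == 0) {
    segments$M <- numeric(0)
    segments$map_mid <- numeric(0)
    return(segments)
  }
  res <- lapply(split(segments, segments$chrom), function(sc) {
    chrom <- sc$chrom[1]
    M <- map_position(recmap, chrom, sc$end) -
      map_position(recmap, chrom, sc$start)
    nsplit <- pmax(1L, ceiling(M / split_M))
    if (any(nsplit > 1L)) {
      idx <- rep(seq_len(nrow(sc)), nsplit)
      off <- sequence(nsplit) - 1L
      k <- nsplit[idx]
      w <- (sc$end - sc$start)[idx]
      start <- floor(sc$start[idx] + off * w / k)
      end <- floor(sc$start[idx] + (off + 1L) * w / k)
      sc <- data.frame(chrom = sc$chrom[idx], start = start, end = end,
                       class = sc$class[idx], stringsAsFactors = FALSE)
      sc <- sc[sc$end > sc$start, , drop = FALSE]
      sc$L <- sc$end - sc$start
    }
    cs <- map_position(recmap, chrom, sc$start)
    ce <- map_position(recmap, chrom, sc$end)
    sc$M <- ce - cs
    sc$map_mid <- map_position(recmap, chrom, (sc$start + sc$end) / 2)
    sc
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("bgs_segments", "data.frame")
  out
}

#' Summarise per-site allele counts into windowed pairwise diversity
#'
#' Each accessible biallelic site with `n = n_ref + n_alt` observed
#' chromosomes contributes `n_ref * n_alt` differing pairwise comparisons to
#' `Y` and `n (n - 1) / 2` total comparisons to `n` in its window;
#' monomorphic accessible sites contribute only to the denominator. Sites
#' with fewer than two observed chromosomes are skipped (and counted).
#'
#' @param counts data frame with `chrom`, `pos` (0-based bp), `n_ref`,
#'   `n_alt`.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window window width in bp (windows tile each chromosome).
#' @param mask optional accessibility track (GRanges); sites outside it
#'   contribute nothing.
#' @return a `bgs_windows` data frame: `chrom`, `start`, `end`, `Y`, `n`,
#'   `accessible_bp`, plus attributes `n_skipped` (sites with n < 2) and a
#'   logical `excluded` column for windows with `n = 0`.
#' @export
windowed_diversity <- function(counts, chrom_lengths, window = 1e6,
                               mask = NULL) {
  stopifnot(all(c("chrom", "pos", "n_ref", "n_alt") %in% names(counts)))
  wins <- tile_windows(chrom_lengths, window)
  if (!is.null(mask)) {
    gr <- GenomicRanges::GRanges(counts$chrom,
                                 IRanges::IRanges(counts$pos + 1L, counts$pos + 1L))
    keep <- IRanges::overlapsAny(gr, mask)
    counts <- counts[keep, , drop = FALSE]
  }
  n <- counts$n_ref + counts$n_alt
  skipped <- sum(n < 2)
  counts <- counts[n >= 2, , drop = FALSE]
  n <- n[n >= 2]
  wid <- match(counts$chrom, names(chrom_lengths))
  widx <- .window_index(wins, counts$chrom, counts$pos)
  ok <- !is.na(widx)
  Y <- rowsum(as.numeric(counts$n_ref * counts$n_alt)[ok], widx[ok])
  Np <- rowsum(as.numeric(n * (n - 1) / 2)[ok], widx[ok])
  wins$Y <- 0; wins$n <- 0
  wins$Y[as.integer(rownames(Y))] <- Y[, 1]
  wins$n[as.integer(rownames(Np))] <- Np[, 1]
  wins$accessible_bp <- .accessible_bp(wins, mask, chrom_lengths)
  wins$excluded <- wins$n == 0
  attr(wins, "n_skipped") <- skipped
  class(wins) <- c("bgs_windows", "data.frame")
  wins
}

#' Tile chromosomes into fixed-width windows
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window window width (bp); the last window of a chromosome is
#'   truncated at its length.
#' @return data frame `chrom`, `start`, `end`.
#' @export
tile_windows <- function(chrom_lengths, window) {
  out <- lapply(names(chrom_lengths), function(ch) {
    st <- seq(0, chrom_lengths[[ch]] - 1, by = window)
    data.frame(chrom = ch, start = st,
               end = pmin(st + window, chrom_lengths[[ch]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.window_index <- function(wins, chrom, pos) {
  # vectorised window lookup: windows are fixed-width tiles per chromosome
  idx <- rep(NA_integer_, length(chrom))
  for (ch in unique(chrom)) {
    rows <- which(wins$chrom == ch)
    if (!length(rows)) next
    w <- wins$start[rows[2]] - wins$start[rows[1]]
    if (is.na(w) || length(rows) == 1) w <- wins$end[rows[1]] - wins$start[rows[1]]
    sel <- chrom == ch
    k <- floor(pos[sel] / w) + 1
    k[k < 1 | k > length(rows)] <- NA
    idx[sel] <- rows[k]
  }
  idx
}

.accessible_bp <- function(wins, mask, chrom_lengths) {
  if (is.null(mask)) return(wins$end - wins$start)
  wgr <- GenomicRanges::GRanges(wins$chrom,
                                IRanges::IRanges(wins$start + 1, wins$end))
  mgr <- GenomicRanges::reduce(mask)
  ov <- GenomicRanges::findOverlaps(wgr, mgr)
  inter <- GenomicRanges::pintersect(wgr[S4Vectors::queryHits(ov)],
                                     mgr[S4Vectors::subjectHits(ov)])
  acc <- numeric(nrow(wins))
  tab <- rowsum(GenomicRanges::width(inter), S4Vectors::queryHits(ov))
  acc[as.integer(rownames(tab))] <- tab[, 1]
  acc
}

#' Write / read windowed diversity as tab-separated text
#' @param windows a `bgs_windows` data frame.
#' @param path file path.
#' @export
write_windows <- function(windows, path) {
  write.table(windows[c("chrom", "start", "end", "Y", "n", "accessible_bp")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  tab$chrom <- as.character(tab$chrom)
  tab$excluded <- tab$n == 0
  class(tab) <- c("bgs_windows", "data.frame")
  tab
}

#' Write / read a segment set as tab-separated text (BED + class column)
#' @param segments a `bgs_segments` data frame.
#' @param path file path.
#' @export
write_segments <- function(segments, path) {
  write.table(segments[c("chrom", "start", "end", "class")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "class"))
  tab$chrom <- as.character(tab$chrom)
  tab$L <- tab$end - tab$start
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("bgs_segments", "data.frame")
  tab
}

#' Write / read a recombination map (cumulative dialect, cM)
#' @param recmap a `bgs_recmap`.
#' @param path file path.
#' @export
write_recmap <- function(recmap, path) {
  df <- do.call(rbind, lapply(names(recmap), function(ch) {
    data.frame(chrom = ch, pos = recmap[[ch]]$pos,
               cum_cM = recmap[[ch]]$cum * 100)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
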