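#' Genome table constructor
#'
#' A genome table is a named numeric vector of chromosome lengths (bp),
#' ordered as given. Used for bounds checks, window clipping, and peak
#' shuffling.
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length positive integer lengths in bp.
#' @return named numeric vector of class `genome_table`.
#' @export
genome_table <- function(chrom, length) {
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  structure(setNames(as.numeric(length), chrom), class = "genome_table")
}

#' Read a two-column chrom-sizes file
#' @param path TSV with columns chrom, length (no header).
#' @return a [genome_table()].
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, col.names = c("chrom", "length"))
  genome_table(dt$chrom, dt$length)
}

#' Read a per-cell fragments file
#'
#' BED3+1 TSV: chrom, start, end, barcode. 0-based half-open coordinates.
#' Gzip-compressed files are handled transparently.
#'
#' @param path fragments file path.
#' @return data.table with columns chrom, start, end, barcode.
#' @export
read_fragments <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "barcode"))
  validate_fragments(dt)
  dt
}

validate_fragments <- function(fragments) {
  stopifnot(all(c("chrom", "start", "end", "barcode") %in% names(fragments)))
  if (any(fragments$start >= fragments$end))
    stop("fragments must satisfy start < end")
  invisible(fragments)
}

#' Write fragments or cut sites as BED
#' @param x data.table with chrom, start, end and one id column.
#' @param path output path.
#' @export
write_bed4 <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Correct an observed barcode against a whitelist
#'
#' The observed barcode is corrected to the best-matching whitelist entry
#' when that entry is within `max_edits` edits and no *other* entry is
#' within `ambiguity_edits` edits; otherwise the read is rejected with a
#' reason code.
#'
#' Barcodes are fixed-length, so Hamming distance is the default edit
#' metric; Levenshtein is available via `metric = "levenshtein"`.
#'
#' @param observed a single DNA string.
#' @param whitelist character vector of known barcodes, all the same length
#'   as `observed` (for the Hamming metric).
#' @param max_edits maximum edits to the best match (default 3).
#' @param ambiguity_edits rejection radius for second-best matches
#'   (default 5).
#' @param metric "hamming" (default) or "levenshtein".
#' @return list with `barcode` (corrected barcode or `NA_character_`) and
#'   `reason` (`NA`, `"no-match"`, or `"ambiguous"`).
#' @export
correct_barcode <- function(observed, whitelist, max_edits = 3,
                            ambiguity_edits = 5,
                            metric = c("hamming", "levenshtein")) {
  metric <- match.arg(metric)
  if (length(whitelist) == 0) stop("whitelist is empty")
  if (length(observed) != 1) stop("observed must be a single barcode")
  if (metric == "hamming") {
    if (any(nchar(whitelist) != nchar(observed)))
      stop("whitelist entries must match the observed barcode length")
    obs <- strsplit(observed, "", fixed = TRUE)[[1]]
    d <- vapply(strsplit(whitelist, "", fixed = TRUE),
                function(w) sum(w != obs), integer(1))
  } else {
    d <- as.integer(utils::adist(observed, whitelist))
  }
  best <- which.min(d)
  if (d[best] > max_edits)
    return(list(barcode = NA_character_, reason = "no-match"))
  if (any(d[-best] <= ambiguity_edits))
    return(list(barcode = NA_character_, reason = "ambiguous"))
  list(barcode = whitelist[best], reason = NA_character_)
}

#' Remove PCR duplicate fragments
#'
#' Fragments with identical (barcode, chrom, start, end) are collapsed to
#' one record. Output is coordinate-sorted.
#'
#' @param fragments data.table of fragments.
#' @return deduplicated data.table.
#' @export
deduplicate_fragments <- function(fragments) {
  dt <- data.table::as.data.table(fragments)
  dt <- unique(dt, by = c("barcode", "chrom", "start", "end"))
  data.table::setorder(dt, chrom, start, end, barcode)
  dt[]
}

#' Remove cells with too few unique fragments
#'
#' @param fragments deduplicated fragments.
#' @param min_fragments minimum unique fragments per barcode (default 150).
#' @return fragments restricted to passing barcodes; the removed barcodes
#'   and their counts are attached as attribute `"removed_cells"`.
#' @export
filter_low_coverage_cells <- function(fragments, min_fragments = 150) {
  dt <- data.table::as.data.table(fragments)
  counts <- dt[, .N, by = barcode]
  bad <- counts[counts$N < min_fragments, ]
  out <- dt[!dt$barcode %in% bad$barcode, ]
  attr(out, "removed_cells") <- as.data.frame(bad)
  if (nrow(bad) > 0)
    message(nrow(bad), " cell barcode(s) removed with < ", min_fragments,
            " fragments")
  out[]
}

#' Convert fragments to Tn5 cut-site windows
#'
#' Each fragment end marks a Tn5 insertion. The insertion point is the
#' fragment start shifted by +4 bp (forward-strand read) and the last
#' covered base (`end - 1`) shifted by -5 bp (reverse-strand read). Each
#' insertion yields a 60-bp window `[center - 30, center + 30)`, clipped at
#' chromosome bounds; zero-width windows after clipping are dropped and
#' counted.
#'
#' @param fragments deduplicated fragments data.table.
#' @param genome a [genome_table()].
#' @param blacklist chromosomes to drop entirely (e.g. `"chrM"`).
#' @param window full window width in bp (default 60).
#' @return data.table of cut sites (chrom, start, end, cell), sorted, with
#'   attribute `"n_zero_width"` counting windows lost to clipping.
#' @export
fragments_to_cutsites <- function(fragments, genome, blacklist = NULL,
                                  window = 60) {
  dt <- data.table::as.data.table(fragments)
  if (!is.null(blacklist)) dt <- dt[!dt$chrom %in% blacklist, ]
  if (nrow(dt) == 0) {
    out <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), cell = character())
    attr(out, "n_zero_width") <- 0L
    return(out)
  }
  unknown <- setdiff(unique(dt$chrom), names(genome))
  if (length(unknown) > 0)
    stop("fragments on chromosomes absent from the genome table: ",
         paste(unknown, collapse = ", "))
  len <- unname(genome[dt$chrom])
  bad <- which(dt$start < 0 | dt$end > len)
  if (length(bad) > 0)
    stop("fragment off chromosome bounds at record ", bad[1], ": ",
         dt$chrom[bad[1]], ":", dt$start[bad[1]], "-", dt$end[bad[1]])
  half <- window %/% 2
  centers <- c(dt$start + 4L, (dt$end - 1L) - 5L)
  cs <- data.table::data.table(
    chrom = rep(dt$chrom, 2),
    start = pmax(centers - half, 0L),
    end   = pmin(centers + half, as.integer(rep(len, 2))),
    cell  = rep(dt$barcode, 2))
  zero <- cs$start >= cs$end
  n_zero <- sum(zero)
  if (n_zero > 0) {
    message(n_zero, " cut-site window(s) dropped as zero-width after clipping")
    cs <- cs[!zero, ]
  }
  data.table::setorder(cs, chrom, start, end, cell)
  attr(cs, "n_zero_width") <- as.integer(n_zero)
  cs[]
}

#' Convert cut sites (or any BED-like table) to GRanges
#' @param x data.table with chrom, start, end and optionally cell.
#' @param genome optional [genome_table()] to set sequence lengths.
#' @return GRanges (1-based closed internally; input is 0-based half-open).
#' @export
bed_to_granges <- function(x, genome = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
  if ("cell" %in% names(x)) gr$cell <- x$cell
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- as.numeric(genome)
  }
  gr
}

#' Convert GRanges back to a 0-based half-open BED table
#' @param gr a GRanges object.
#' @return data.table chrom, start, end (plus name column if present).
#' @export
granges_to_bed <- function(gr) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr))
  if (!is.null(gr$cell)) dt$cell <- gr$cell
  dt
}
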