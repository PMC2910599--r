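# Readers and writers for the on-disk formats: probe tables (TSV),
# segments (IGV SEG), intervals (BED), statistics (TSV), audit (JSON).
# All writes are atomic (temp file + rename) and numbers are formatted to
# six significant digits so repeated runs are byte-identical.

# internal: atomic write of a character vector of lines
.writeLines <- function(lines, path) {
    tmp <- tempfile(tmpdir = dirname(path))
    con <- file(tmp, open = "wb")
    writeLines(lines, con, sep = "\n")
    close(con)
    file.rename(tmp, path)
    invisible(path)
}

# internal: format numbers at fixed precision for stable outputs
.fmt <- function(x) {
    if (is.double(x)) ifelse(is.na(x), "NA", sprintf("%.6g", x))
    else as.character(x)
}

# internal: data.frame -> TSV lines
.tsvLines <- function(df) {
    cols <- vapply(df, function(col) .fmt(col), character(nrow(df)))
    if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1L)
    c(paste(names(df), collapse = "\t"),
      apply(cols, 1L, paste, collapse = "\t"))
}

#' Write a data.frame as a TSV file (atomic, fixed precision)
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTsv <- function(df, path) {
    if (!nrow(df)) return(.writeLines(paste(names(df), collapse = "\t"),
                                      path))
    .writeLines(.tsvLines(df), path)
}

#' Read a probe table into an AcghProfile
#'
#' Expected tab-delimited header:
#' `clone_id chrom start end log2_rep1 .. log2_repK sd snr`. Input
#' coordinates are 0-based half-open by default; `oneBased = TRUE` accepts
#' 1-based inclusive coordinates and converts them.
#'
#' @param path TSV file.
#' @param sampleName sample id (default: file name without extension).
#' @param oneBased whether input coordinates are 1-based inclusive.
#' @return an [AcghProfile-class].
#' @export
readProbeTable <- function(path, sampleName = NULL, oneBased = FALSE) {
    if (is.null(sampleName))
        sampleName <- sub("\\.[^.]*$", "", basename(path))
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    repCols <- grep("^log2_rep", names(df), value = TRUE)
    need <- c("clone_id", "chrom", "start", "end", "sd", "snr")
    if (!all(need %in% names(df)) || !length(repCols))
        stop("probe table '", path, "' lacks required columns (",
             paste(need, collapse = ", "), ", log2_rep*)")
    if (oneBased) df$start <- df$start - 1L
    bad <- which(df$start >= df$end)
    if (length(bad))
        stop("probe table '", path, "': start >= end at line ",
             bad[1L] + 1L)
    dup <- which(duplicated(df$clone_id))
    if (length(dup))
        stop("probe table '", path, "': duplicate clone id '",
             df$clone_id[dup[1L]], "' at line ", dup[1L] + 1L)
    AcghProfile(sampleName = sampleName, cloneId = df$clone_id,
                chrom = df$chrom, start = df$start, end = df$end,
                replicates = as.matrix(df[, repCols, drop = FALSE]),
                replicateSD = df$sd, snr = df$snr)
}

#' Write an AcghProfile as a probe table
#'
#' Inverse of [readProbeTable()] (0-based half-open coordinates).
#'
#' @param profile an [AcghProfile-class].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeProbeTable <- function(profile, path) {
    bp <- .bpBounds(profile@clones)
    reps <- profile@replicates
    colnames(reps) <- paste0("log2_rep", seq_len(ncol(reps)))
    df <- cbind(data.frame(clone_id = profile@clones$cloneId,
                           chrom = bp$chrom, start = bp$start,
                           end = bp$end),
                as.data.frame(reps),
                data.frame(sd = profile@replicateSD, snr = profile@snr))
    writeTsv(df, path)
}

#' Write a segmented profile in IGV SEG format
#'
#' Columns: sample, chrom, loc.start, loc.end, num.mark, seg.mean
#' (1-based inclusive coordinates, the SEG convention).
#'
#' @param seg a [SegmentedProfile-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSeg <- function(seg, path) {
    sg <- seg@segments
    chrom <- as.character(seqnames(seg@clones))
    df <- data.frame(
        sample = seg@sampleName,
        chrom = chrom[sg$startIndex],
        loc.start = start(seg@clones)[sg$startIndex],
        loc.end = end(seg@clones)[sg$endIndex],
        num.mark = sg$endIndex - sg$startIndex + 1L,
        seg.mean = sg$mean)
    .writeLines(c(paste(c("sample", "chrom", "loc.start", "loc.end",
                          "num.mark", "seg.mean"), collapse = "\t"),
                  .tsvLines(df)[-1L]), path)
}

#' Write genomic intervals as BED (0-based half-open)
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally a
#'   score column named by `scoreCol`; rows are sorted by (chrom, start).
#' @param path output file.
#' @param scoreCol optional numeric column written as the BED score field
#'   (a `name` field of `.` is inserted as required by the format).
#' @param trackName optional `track name=` header comment.
#' @return the path, invisibly.
#' @export
writeBed <- function(df, path, scoreCol = NULL, trackName = NULL) {
    header <- if (!is.null(trackName))
        sprintf("track name=%s", trackName) else "# BED 0-based half-open"
    if (!nrow(df)) return(.writeLines(header, path))
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    stopifnot(all(df$start < df$end))
    lines <- if (is.null(scoreCol))
        sprintf("%s\t%d\t%d", df$chrom, as.integer(df$start),
                as.integer(df$end))
    else
        sprintf("%s\t%d\t%d\t.\t%s", df$chrom, as.integer(df$start),
                as.integer(df$end), .fmt(as.double(df[[scoreCol]])))
    .writeLines(c(header, lines), path)
}

#' Read an expression panel from TSV files
#'
#' @param exprPath probes x samples TSV (first column `probe_id`, one
#'   column per sample).
#' @param mapPath probe map TSV with columns
#'   `probe_id gene chrom start end` (0-based half-open).
#' @param labelsPath two-column TSV `sample cohort`.
#' @param scale value scale (default `"log10"`).
#' @return an [ExpressionPanel-class].
#' @export
readExpressionPanel <- function(exprPath, mapPath, labelsPath,
                                scale = "log10") {
    ex <- utils::read.delim(exprPath, check.names = FALSE,
                            stringsAsFactors = FALSE)
    pm <- utils::read.delim(mapPath, stringsAsFactors = FALSE)
    lb <- utils::read.delim(labelsPath, stringsAsFactors = FALSE)
    m <- as.matrix(ex[, -1L, drop = FALSE])
    rownames(m) <- ex[[1L]]
    o <- match(ex[[1L]], pm$probe_id)
    if (anyNA(o)) stop("probes missing from the probe map")
    cohorts <- lb$cohort[match(colnames(m), lb$sample)]
    if (anyNA(cohorts)) stop("samples missing from the label file")
    ExpressionPanel(m,
        data.frame(probeId = pm$probe_id[o], gene = pm$gene[o],
                   chrom = pm$chrom[o], start = pm$start[o],
                   end = pm$end[o]),
        cohorts, scale = scale)
}

#' Write an expression panel (expression, probe map, labels)
#'
#' @param panel an [ExpressionPanel-class].
#' @param exprPath,mapPath,labelsPath output TSV paths.
#' @return invisibly, the three paths.
#' @export
writeExpressionPanel <- function(panel, exprPath, mapPath, labelsPath) {
    df <- cbind(data.frame(probe_id = panel@probeMap$probeId),
                as.data.frame(panel@exprs))
    writeTsv(df, exprPath)
    pm <- panel@probeMap
    writeTsv(data.frame(probe_id = pm$probeId, gene = pm$gene,
                        chrom = pm$chrom, start = pm$start, end = pm$end),
             mapPath)
    writeTsv(data.frame(sample = colnames(panel@exprs),
                        cohort = as.character(panel@cohorts)), labelsPath)
    invisible(c(exprPath, mapPath, labelsPath))
}

#' Write a JSON audit file (atomic)
#'
#' @param x list to serialise.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAuditJson <- function(x, path) {
    .writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 6,
                                 pretty = TRUE, na = "null"),
                path)
}
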