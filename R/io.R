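# Readers and writers. Event tables are TSV with unit-bearing column
# names (position_kbp, t_start_s, ...) to prevent unit drift; sequence
# coordinates are 1-based inclusive in reports and 0-based half-open
# internally. GroundTruth and configuration travel as YAML side-cars.

#' Read a FASTA file of DNA (or RNA-as-DNA) sequences
#'
#' Standard multi-line FASTA parsing with uppercase normalization;
#' optionally converts U to T so RNA sequences can be handled as DNA.
#'
#' @param path FASTA file.
#' @param rna_as_dna convert U to T.
#' @return a \code{\link[Biostrings]{DNAStringSet}}.
#' @export
readGenomeFasta <- function(path, rna_as_dna = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0) stop("empty FASTA file: ", path)
    raw <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("malformed FASTA (", path,
                                             "): ", conditionMessage(e)))
    if (!length(raw)) stop("no records in FASTA file: ", path)
    ch <- toupper(as.character(raw))
    if (rna_as_dna) ch <- gsub("U", "T", ch, fixed = TRUE)
    out <- Biostrings::DNAStringSet(ch)
    names(out) <- names(raw)
    out
}

#' Read and validate a typed event table
#'
#' Reads a TSV with header, validates the declared column types, reports
#' rejected rows (rows failing a supplied predicate) and preserves extra
#' columns with a warning.
#'
#' @param path TSV file.
#' @param schema named character vector mapping required column names to
#'   types (\code{"numeric"}, \code{"integer"}, \code{"character"},
#'   \code{"logical"}).
#' @param reject optional function(data.frame) returning a logical
#'   vector of rows to reject.
#' @return the validated data.frame with attributes \code{"n_read"} and
#'   \code{"n_rejected"}.
#' @export
readEventTable <- function(path, schema, reject = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    miss <- setdiff(names(schema), names(df))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    extra <- setdiff(names(df), names(schema))
    if (length(extra))
        warning("extra column(s) preserved: ", paste(extra, collapse = ", "))
    for (cn in names(schema)) {
        df[[cn]] <- switch(schema[[cn]],
                           numeric = as.numeric(df[[cn]]),
                           integer = as.integer(df[[cn]]),
                           character = as.character(df[[cn]]),
                           logical = as.logical(df[[cn]]),
                           stop("unknown schema type: ", schema[[cn]]))
    }
    n0 <- nrow(df)
    nrej <- 0L
    if (!is.null(reject)) {
        bad <- reject(df)
        nrej <- sum(bad)
        if (nrej) {
            warning(nrej, " row(s) rejected by validation")
            df <- df[!bad, , drop = FALSE]
        }
    }
    attr(df, "n_read") <- n0
    attr(df, "n_rejected") <- nrej
    df
}

.curtainSchema <- c(event = "integer", experiment = "character",
                    fov = "character", dna = "integer",
                    position_kbp = "numeric", t_start_s = "numeric",
                    t_end_s = "numeric", censored = "logical",
                    channel = "character", amplitude = "numeric",
                    partner_event = "integer")

#' Write / read a curtain event table as TSV
#'
#' @param table a \code{\linkS4class{CurtainEventTable}}.
#' @param path TSV file.
#' @return \code{readCurtainEvents} returns a
#'   \code{\linkS4class{CurtainEventTable}}; rows with non-positive
#'   dwell are rejected and reported.
#' @export
writeCurtainEvents <- function(table, path) {
    write.table(curtainEvents(table), path, sep = "\t", row.names = FALSE,
                quote = FALSE)
    invisible(path)
}

#' @rdname writeCurtainEvents
#' @param movie_length,genome_length_kbp table attributes (required on
#'   read; the movie length defines censoring).
#' @export
readCurtainEvents <- function(path, movie_length, genome_length_kbp) {
    df <- readEventTable(path, .curtainSchema,
                         reject = function(d)
                             !is.finite(d$t_start_s) | !is.finite(d$t_end_s) |
                             d$t_end_s - d$t_start_s <= 0 |
                             d$position_kbp < 0)
    new("CurtainEventTable", events = df, movieLength = movie_length,
        genomeLengthKbp = genome_length_kbp, groundTruth = NULL)
}

#' Write / read a spot table as TSV
#'
#' @param spots a \code{\linkS4class{SpotTable}}.
#' @param path TSV file.
#' @export
writeSpotTable <- function(spots, path) {
    write.table(spotData(spots), path, sep = "\t", row.names = FALSE,
                quote = FALSE)
    invisible(path)
}

#' @rdname writeSpotTable
#' @export
readSpotTable <- function(path) {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    new("SpotTable", spots = df, metadata = list(source = path))
}

#' Write / read ground truth (or any configuration list) as YAML
#'
#' @param truth named list.
#' @param path YAML file.
#' @export
writeGroundTruth <- function(truth, path) {
    yaml::write_yaml(truth, path)
    invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
    yaml::read_yaml(path)
}

#' Write a multi-channel 3D stack as multi-page TIFF (channel-major,
#' then z)
#'
#' Intensities are stored as 32-bit float pages; channel order and shape
#' go into a YAML side-car so the reader can reassemble the arrays.
#'
#' @param images named list of 3D arrays, dim \code{c(z, y, x)}.
#' @param path TIFF file.
#' @return invisibly, the side-car path.
#' @export
writeTiffStack <- function(images, path) {
    pages <- list()
    for (ch in names(images)) {
        arr <- images[[ch]]
        for (z in seq_len(dim(arr)[1]))
            pages[[length(pages) + 1L]] <- arr[z, , ]
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    side <- paste0(path, ".yaml")
    yaml::write_yaml(list(channels = names(images),
                          shape = as.integer(dim(images[[1]]))), side)
    invisible(side)
}

#' @rdname writeTiffStack
#' @export
readTiffStack <- function(path) {
    meta <- yaml::read_yaml(paste0(path, ".yaml"))
    pages <- tiff::readTIFF(path, all = TRUE)
    nz <- meta$shape[1]
    out <- list()
    for (i in seq_along(meta$channels)) {
        arr <- array(0, dim = meta$shape)
        for (z in seq_len(nz))
            arr[z, , ] <- pages[[(i - 1L) * nz + z]]
        out[[meta$channels[i]]] <- arr
    }
    out
}

#' Write a labelled ROI mask as 16-bit TIFF
#'
#' @param mask integer label matrix.
#' @param path TIFF file.
#' @export
writeMaskTiff <- function(mask, path) {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
    invisible(path)
}

#' @rdname writeMaskTiff
#' @export
readMaskTiff <- function(path) {
    m <- tiff::readTIFF(path)
    storage.mode(m) <- "double"
    round(m * 65535)
}

#' Write a histogram object as CSV
#'
#' @param hist a \code{\linkS4class{MassHistogram}} or
#'   \code{\linkS4class{PositionHistogram}}.
#' @param path CSV file.
#' @export
writeHistogramCsv <- function(hist, path) {
    df <- data.frame(lower = head(hist@breaks, -1),
                     upper = tail(hist@breaks, -1),
                     count = hist@counts)
    if (is(hist, "MassHistogram") && length(hist@smoothed))
        df$smoothed <- hist@smoothed
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    invisible(path)
}
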