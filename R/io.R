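# Readers and writers for FASTA, GFF3, BED6 and expression tables.
# Internal coordinates are 0-based half-open; GFF3 (1-based inclusive) is
# converted here and nowhere else.

#' Read sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @param alphabet `"nt"` for nucleotide, `"aa"` for peptide records.
#' @return Named character vector of uppercased residues, in file order.
#' @export
read_sequences <- function(path, alphabet = c("nt", "aa")) {
    alphabet <- match.arg(alphabet)
    if (!file.exists(path)) stop("no such file: ", path)
    set <- Biostrings::readBStringSet(path)
    if (any(Biostrings::width(set) == 0L)) {
        bad <- which(Biostrings::width(set) == 0L)[1]
        stop(sprintf("empty sequence for record '%s' (record %d)",
                     names(set)[bad], bad))
    }
    seqs <- toupper(as.character(set))
    ids <- sub("\\s.*$", "", names(set))
    if (any(!nzchar(ids))) stop("malformed FASTA header (empty id)")
    names(seqs) <- ids
    seqs
}

#' Write sequences to a FASTA file
#'
#' Records are wrapped at 60 columns.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_sequences <- function(seqs, path) {
    stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
    set <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(set, path, width = 60L)
    invisible(path)
}

#' Read genomic features from GFF3 or BED
#'
#' GFF3 coordinates (1-based inclusive) are converted to the package's
#' internal 0-based half-open convention; BED is already 0-based half-open
#' and passes through. GFF3 column-9 attributes are preserved as named
#' character vectors in the `attributes` list-column.
#'
#' @param path input file.
#' @param format `"gff3"` or `"bed"`.
#' @param chrom_lengths optional named vector; features on chromosomes not
#'   in it are rejected with an error rather than silently dropped.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand` plus
#'   format-specific columns (`source`, `type`, `score`, `attributes`, `id`
#'   for GFF3; `name`, `score` for BED).
#' @export
read_features <- function(path, format = c("gff3", "bed"),
                          chrom_lengths = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) == 0L) {
        out <- data.frame(chrom = character(), start = integer(),
                          end = integer(), strand = character())
        return(out)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (format == "gff3") {
        nf <- lengths(fields)
        if (any(nf != 9L)) {
            stop(sprintf("GFF3 line %d: expected 9 columns, got %d",
                         which(nf != 9L)[1], nf[nf != 9L][1]))
        }
        m <- do.call(rbind, fields)
        start <- as.integer(m[, 4]) - 1L
        end <- as.integer(m[, 5])
        if (any(is.na(start)) || any(is.na(end))) {
            stop("GFF3: non-numeric coordinates")
        }
        bad <- which(end <= start)
        if (length(bad) > 0) {
            stop(sprintf("GFF3 line %d: end < start after conversion", bad[1]))
        }
        attrs <- lapply(m[, 9], parse_gff3_attributes)
        ids <- vapply(attrs, function(a) {
            if ("ID" %in% names(a)) a[["ID"]] else NA_character_
        }, character(1))
        out <- data.frame(chrom = m[, 1], source = m[, 2], type = m[, 3],
                          start = start, end = end,
                          score = m[, 6], strand = m[, 7],
                          id = ids, stringsAsFactors = FALSE)
        out$attributes <- I(attrs)
    } else {
        m <- do.call(rbind, lapply(fields, function(f) {
            length(f) <- 6L
            f
        }))
        out <- data.frame(chrom = m[, 1],
                          start = as.integer(m[, 2]),
                          end = as.integer(m[, 3]),
                          name = ifelse(is.na(m[, 4]), ".", m[, 4]),
                          score = ifelse(is.na(m[, 5]), ".", m[, 5]),
                          strand = ifelse(is.na(m[, 6]), ".", m[, 6]),
                          stringsAsFactors = FALSE)
        bad <- which(out$end <= out$start)
        if (length(bad) > 0) {
            stop(sprintf("BED line %d: end <= start", bad[1]))
        }
    }
    validate_intervals(out, chrom_lengths)
    rownames(out) <- NULL
    out
}

parse_gff3_attributes <- function(x) {
    if (is.na(x) || x == "." || !nzchar(x)) return(character(0))
    parts <- strsplit(x, ";", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    kv <- regmatches(parts, regexpr("=", parts, fixed = TRUE), invert = TRUE)
    vals <- vapply(kv, function(p) if (length(p) == 2) p[2] else "", character(1))
    names(vals) <- vapply(kv, `[`, character(1), 1)
    vals
}

format_gff3_attributes <- function(a) {
    if (length(a) == 0L) return(".")
    paste(paste0(names(a), "=", a), collapse = ";")
}

#' Write genomic features to GFF3 or BED
#'
#' Inverse of [read_features()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive for GFF3.
#'
#' @param features data.frame as returned by [read_features()].
#' @param path output path.
#' @param format `"gff3"` or `"bed"`.
#' @export
write_features <- function(features, path, format = c("gff3", "bed")) {
    format <- match.arg(format)
    if (format == "gff3") {
        src <- if ("source" %in% names(features)) features$source else "tescape"
        typ <- if ("type" %in% names(features)) features$type else "region"
        sco <- if ("score" %in% names(features)) features$score else "."
        att <- if ("attributes" %in% names(features)) {
            vapply(features$attributes, format_gff3_attributes, character(1))
        } else if ("id" %in% names(features)) {
            paste0("ID=", features$id)
        } else "."
        lines <- paste(features$chrom, src, typ, features$start + 1L,
                       features$end, sco, features$strand, ".", att,
                       sep = "\t")
        writeLines(c("##gff-version 3", lines), path)
    } else {
        nm <- if ("name" %in% names(features)) features$name else "."
        sco <- if ("score" %in% names(features)) features$score else "."
        std <- if ("strand" %in% names(features)) features$strand else "."
        lines <- paste(features$chrom, features$start, features$end,
                       nm, sco, std, sep = "\t")
        writeLines(lines, path)
    }
    invisible(path)
}

#' Reads per kilobase per million mapped reads
#'
#' @param raw_count read count(s) for the feature.
#' @param feature_length feature length in bp (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return `raw_count * 1e9 / (feature_length * library_size)`.
#' @examples
#' rpkm(100, 1000, 1e6) # 100
#' @export
rpkm <- function(raw_count, feature_length, library_size) {
    if (any(feature_length <= 0)) stop("feature_length must be > 0")
    if (any(library_size <= 0)) stop("library_size must be > 0")
    if (any(raw_count < 0)) stop("raw_count must be >= 0")
    raw_count * 1e9 / (feature_length * library_size)
}

#' Read an expression table
#'
#' Tab-separated with header `feature_id<TAB>count<TAB>rpkm`.
#'
#' @param path input TSV.
#' @return data.frame with columns `feature_id`, `count`, `rpkm`.
#' @export
read_expression <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("feature_id", "count", "rpkm")
    if (!all(need %in% names(df))) {
        stop("expression table must have columns: ", paste(need, collapse = ", "))
    }
    if (any(df$count < 0) || any(df$rpkm < 0)) {
        stop("negative expression values")
    }
    df[need]
}

#' Write an expression table
#'
#' @param expr data.frame with columns `feature_id`, `count`, `rpkm`.
#' @param path output TSV.
#' @export
write_expression <- function(expr, path) {
    utils::write.table(expr[c("feature_id", "count", "rpkm")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
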