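# Interval arithmetic on 0-based half-open coordinates.

#' Total length of the union of a set of intervals
#'
#' @param starts,ends integer vectors of interval bounds (0-based half-open).
#' @return Total number of positions covered by at least one interval.
#' @examples
#' interval_union_length(c(0, 50), c(100, 150))
#' @export
interval_union_length <- function(starts, ends) {
    m <- merge_intervals(starts, ends)
    sum(m$end - m$start)
}

#' Merge overlapping or book-ended intervals
#'
#' @param starts,ends interval bounds (0-based half-open).
#' @return data.frame with columns `start`, `end` of the merged set, sorted.
#' @export
merge_intervals <- function(starts, ends) {
    stopifnot(length(starts) == length(ends))
    if (length(starts) == 0L) {
        return(data.frame(start = integer(), end = integer()))
    }
    if (any(ends < starts)) stop("interval end < start")
    o <- order(starts, ends)
    s <- starts[o]
    e <- ends[o]
    ms <- s[1]
    me <- e[1]
    out_s <- numeric(0)
    out_e <- numeric(0)
    for (i in seq_along(s)[-1]) {
        if (s[i] <= me) {
            me <- max(me, e[i])
        } else {
            out_s <- c(out_s, ms)
            out_e <- c(out_e, me)
            ms <- s[i]
            me <- e[i]
        }
    }
    data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# overlap length of one interval [s, e) with a set of intervals
overlap_with_set <- function(s, e, starts, ends) {
    if (length(starts) == 0L) return(0)
    sum(pmax(0, pmin(e, ends) - pmax(s, starts)))
}

# midpoint convention used for window membership throughout
interval_midpoint <- function(start, end) {
    floor((start + end) / 2)
}

validate_intervals <- function(df, chrom_lengths = NULL, what = "feature") {
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
    bad <- which(df$end <= df$start | df$start < 0)
    if (length(bad) > 0) {
        stop(sprintf("%s %d: invalid interval [%s, %s)", what, bad[1],
                     df$start[bad[1]], df$end[bad[1]]))
    }
    if (!is.null(chrom_lengths)) {
        unknown <- setdiff(unique(df$chrom), names(chrom_lengths))
        if (length(unknown) > 0) {
            stop(sprintf("%s on unknown chromosome(s): %s", what,
                         paste(unknown, collapse = ", ")))
        }
        over <- which(df$end > chrom_lengths[df$chrom])
        if (length(over) > 0) {
            stop(sprintf("%s %d extends past end of %s", what, over[1],
                         df$chrom[over[1]]))
        }
    }
    invisible(df)
}
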