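#' Retain species by occurrence thresholds
#'
#' A species is retained if it was ringed (count > 0) in at least
#' `min_years` distinct years **or** on at least `min_islands` distinct
#' islands. The disjunction keeps regular but localized species as well as
#' widespread but sporadic ones, while dropping accidental captures.
#'
#' @param records a `capture_records` data frame.
#' @param min_years minimum number of distinct years with captures.
#' @param min_islands minimum number of distinct islands with captures.
#' @return list with `records` (filtered, class kept) and `dropped`
#'   (character vector of excluded species).
#' @export
filter_species <- function(records, min_years = 5, min_islands = 5) {
  pos <- records[records$count > 0, , drop = FALSE]
  yrs <- tapply(pos$year, pos$species, function(y) length(unique(y)))
  isl <- tapply(pos$island, pos$species, function(i) length(unique(i)))
  sp <- sort(unique(records$species))
  ny <- ifelse(is.na(yrs[sp]), 0L, yrs[sp])
  ni <- ifelse(is.na(isl[sp]), 0L, isl[sp])
  keep <- sp[ny >= min_years | ni >= min_islands]
  dropped <- setdiff(sp, keep)
  out <- records[records$species %in% keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("filter_species: no species left after filtering")
  class(out) <- class(records)
  list(records = out, dropped = dropped)
}

#' Eligible island-years from ringing effort
#'
#' An island-year is eligible when the station ran on at least
#' `min_days` distinct days in *each* fortnight of the standard spring
#' window (16-30 April and 1-15 May by default), i.e. at least one week of
#' ringing in the fortnight of each month.
#'
#' @param effort an `effort_records` data frame (island, date, net_length).
#' @param window character vector of two `MM-DD` strings giving the start of
#'   the first fortnight and end of the second (defaults 16 Apr / 15 May).
#' @param min_days minimum distinct ringing days required per fortnight.
#' @return data frame with columns `island`, `year`.
#' @export
filter_years <- function(effort, window = c("04-16", "05-15"), min_days = 7) {
  md <- format(effort$date, "%m-%d")
  in_win <- md >= window[1] & md <= window[2]
  n_out <- sum(!in_win)
  if (n_out > 0)
    message("filter_years: ignoring ", n_out, " effort day(s) outside the season window")
  e <- effort[in_win, , drop = FALSE]
  if (nrow(e) == 0L) return(data.frame(island = character(), year = integer()))
  year <- as.integer(format(e$date, "%Y"))
  fortnight <- ifelse(format(e$date, "%m-%d") <= "04-30", "apr", "may")
  key <- interaction(e$island, year, drop = TRUE)
  ok <- tapply(seq_len(nrow(e)), key, function(ix) {
    f <- fortnight[ix]
    d <- as.character(e$date[ix])
    length(unique(d[f == "apr"])) >= min_days &&
      length(unique(d[f == "may"])) >= min_days
  })
  keys <- names(ok)[unlist(ok)]
  if (length(keys) == 0L) return(data.frame(island = character(), year = integer()))
  parts <- do.call(rbind, strsplit(keys, ".", fixed = TRUE))
  out <- data.frame(island = parts[, 1], year = as.integer(parts[, 2]))
  out[order(out$island, out$year), , drop = FALSE]
}

#' Pivot capture records to an island-year x species matrix
#'
#' Missing (island, year, species) combinations become 0. Island-years
#' whose row total is zero are removed with a warning (the chord transform
#' is undefined for empty samples).
#'
#' @param records a `capture_records` data frame.
#' @return a `community_matrix`: numeric matrix (rows island-year samples,
#'   columns species) with attribute `meta`, a data frame of `island` and
#'   `year` per row.
#' @export
pivot_records <- function(records) {
  isl <- sort(unique(records$island))
  key <- paste(records$island, records$year, sep = "_")
  rows <- sort(unique(key))
  sp <- sort(unique(records$species))
  m <- matrix(0, length(rows), length(sp), dimnames = list(rows, sp))
  m[cbind(match(key, rows), match(records$species, sp))] <- records$count
  meta <- data.frame(
    island = sub("_[^_]+$", "", rows),
    year = as.integer(sub("^.*_", "", rows)),
    row.names = rows, stringsAsFactors = FALSE)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning("pivot_records: dropping all-zero island-year(s): ",
            paste(rows[zero], collapse = ", "))
    m <- m[!zero, , drop = FALSE]
    meta <- meta[!zero, , drop = FALSE]
  }
  structure(m, meta = meta, class = c("community_matrix", class(m)))
}

#' Sample metadata of a community or chord matrix
#'
#' @param x a `community_matrix` or `chord_matrix`.
#' @return data frame with columns `island` and `year`, one row per sample.
#' @export
sample_meta <- function(x) attr(x, "meta")

#' Chord transformation
#'
#' Scales every row of the community matrix to unit Euclidean norm,
#' \eqn{y'_{rj} = y_{rj} / \sqrt{\sum_j y_{rj}^2}}, so that Euclidean
#' distances between transformed rows are chord distances (range
#' \eqn{[0, \sqrt 2]}). The transform is invariant to multiplying a row by
#' a positive scalar: it turns counts into a relative-composition index.
#'
#' @param m a `community_matrix` (or plain non-negative matrix).
#' @return a `chord_matrix` with the same shape and metadata.
#' @examples
#' chord_transform(rbind(c(3, 4)))  # -> 0.6 0.8
#' @export
chord_transform <- function(m) {
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) {
    bad <- rownames(m)[norms == 0]
    stop("chord_transform: zero row(s): ", paste(bad, collapse = ", "))
  }
  out <- m / norms
  structure(as.matrix(out), meta = attr(m, "meta"),
            class = c("chord_matrix", "matrix", "array"))
}
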