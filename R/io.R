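#' Read long-format capture records
#'
#' Reads a CSV of ringing totals with columns `island`, `year`, `species`,
#' `count` (one row per island x year x species) and validates it: counts
#' must be non-negative integers and the (island, year, species) key unique.
#'
#' @param path path to a CSV file with header `island,year,species,count`.
#' @return A data frame of class `capture_records`.
#' @seealso [pivot_records()], [filter_species()]
#' @export
read_capture_records <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  as_capture_records(x)
}

#' Validate a data frame of capture records
#'
#' @param x data frame with columns `island`, `year`, `species`, `count`.
#' @return `x` with class `capture_records` prepended.
#' @export
as_capture_records <- function(x) {
  need <- c("island", "year", "species", "count")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("capture records: missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) stop("capture records: at least one record required")
  x$year <- as.integer(x$year)
  x$count <- as.numeric(x$count)
  if (anyNA(x$year)) stop("capture records: non-integer year")
  if (anyNA(x$count) || any(x$count < 0))
    stop("capture records: negative count or missing count")
  if (any(x$count != round(x$count)))
    stop("capture records: counts must be integers")
  key <- paste(x$island, x$year, x$species, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("capture records: duplicate key (%s, %d, %s)",
                 d$island, d$year, d$species))
  }
  class(x) <- c("capture_records", "data.frame")
  x
}

#' Read daily ringing-effort records
#'
#' CSV with columns `island`, `date` (ISO `YYYY-MM-DD`), `net_length`
#' (metres of mist net open that day, > 0).
#'
#' @param path path to the CSV file.
#' @return data frame of class `effort_records` with `date` as `Date`.
#' @export
read_effort_records <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("island", "date", "net_length")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("effort records: missing column(s): ", paste(miss, collapse = ", "))
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("effort records: unparseable date")
  if (any(x$net_length <= 0)) stop("effort records: net_length must be > 0")
  class(x) <- c("effort_records", "data.frame")
  x
}

#' Read an island descriptor table
#'
#' One row per island; geographic columns (`Latitude`, `LongKm`,
#' `MinDistAfrica`, `StrDistAfrica`, `MinDistLand`, `MinDSouthLand`, all
#' distances in km) and habitat columns (`Area` in km^2, `MaxAlt` in m,
#' `NDVI` unitless in \[-1, 1\]).
#'
#' @param path path to the CSV file; defaults to the packaged nine-island
#'   western Mediterranean table (see [island_descriptors()]).
#' @return data frame with islands as rows.
#' @export
read_island_descriptors <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!"island" %in% names(x)) stop("island descriptors: missing 'island' column")
  if (anyDuplicated(x$island)) stop("island descriptors: duplicated island")
  num <- c("Area", "MaxAlt", "MinDistAfrica", "StrDistAfrica",
           "MinDistLand", "MinDSouthLand")
  for (v in intersect(num, names(x)))
    if (any(x[[v]] < 0)) stop("island descriptors: negative ", v)
  if ("NDVI" %in% names(x) && any(abs(x$NDVI) > 1))
    stop("island descriptors: NDVI outside [-1, 1]")
  rownames(x) <- x$island
  x
}

#' Nine-island descriptor table
#'
#' The packaged descriptor table for the nine western Mediterranean islands
#' with standardized spring ringing stations (Aire, Cabrera, Formentera,
#' Colom, Columbrets, Conillera, Dragonera, Grosa, Tabarca), including the
#' published per-island mean local contribution to beta diversity (`LCBD`)
#' and island temporal beta diversity (`BDTi`) columns.
#'
#' @return data frame with one row per island.
#' @examples
#' isl <- island_descriptors()
#' cor(isl$LCBD, isl$BDTi)
#' @export
island_descriptors <- function() {
  path <- system.file("extdata", "island_descriptors.csv",
                      package = "migcomp", mustWork = TRUE)
  read_island_descriptors(path)
}

#' Read a species trait table
#'
#' CSV with columns `species`, `kipp_mean`, `kipp_sd` (Kipp wing-pointedness
#' index, percent) and optionally `war` (wing aspect ratio; may be missing
#' for some species).
#'
#' @param path path to the CSV file.
#' @return data frame with species as rownames.
#' @export
read_trait_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "kipp_mean")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("trait table: missing column(s): ", paste(miss, collapse = ", "))
  if (any(x$kipp_mean <= 0 | x$kipp_mean >= 100))
    stop("trait table: kipp_mean must lie in (0, 100)")
  rownames(x) <- x$species
  x
}

#' Read a phylogenetic tree in Newick format
#'
#' Thin validating wrapper around [ape::read.tree()]: requires a single
#' rooted tree with branch lengths and positive root-to-tip depths.
#'
#' @param path path to a Newick file (or a Newick string via `text`).
#' @param text optional Newick string, passed to [ape::read.tree()].
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(file = path, text = text)),
    error = function(e) NULL)
  if (is.null(tr)) stop("newick: parse error (unbalanced parentheses?)")
  if (inherits(tr, "multiPhylo")) stop("newick: expected a single tree")
  if (is.null(tr$edge.length)) stop("newick: tree has no branch lengths")
  depths <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
  if (any(depths <= 0)) stop("newick: zero root-to-tip path length")
  tr
}
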