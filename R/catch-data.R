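# Reading, validating and reshaping trap-night catch records.

#' Trap codes recognised by the package
#'
#' The closed vocabulary of trap codes: HLC (human landing catch, the
#' reference method), SUN (Suna trap), BGS (BG-Sentinel), ITTC (Ifakara Tent
#' Trap C), MMX (Mosquito Magnet-X), MTR (M-Trap) and MTRC (M-Trap with a CDC
#' light trap). Hyphens and case are ignored on input, so `"ITT-C"` and
#' `"ittc"` both normalise to `"ITTC"`.
#'
#' @format Character vector of length 7.
#' @export
trap_codes <- c("HLC", "SUN", "BGS", "ITTC", "MMX", "MTR", "MTRC")

normalize_trap <- function(x) toupper(gsub("-", "", trimws(x), fixed = TRUE))

# Hours run overnight: 18..23 then 0..5.
valid_hours <- c(18:23, 0:5)

#' Read a long-format catch CSV into validated trap-night records
#'
#' The expected schema has columns `date` (ISO-8601), `village`, `trap`
#' (one of [trap_codes], hyphens ignored), `taxon`, `hour` (optional, integer
#' 18--23 or 0--5; blank for already-nightly rows) and `count` (non-negative
#' integer, female mosquitoes). Every row becomes one record; row order is
#' preserved and a parse report is emitted as a message.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @return A data frame of class `"catch_records"` with columns `date`
#'   (`Date`), `village`, `trap`, `taxon` (character), `hour` (integer, `NA`
#'   for nightly rows) and `count` (integer).
#' @seealso [pool_hourly()], [build_catch_table()], [write_catch_csv()]
#' @export
read_catch_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("date", "village", "trap", "taxon", "count")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  if (!("hour" %in% names(raw))) raw$hour <- NA_character_
  if (nrow(raw) == 0) {
    warning("no data rows in ", path)
    message("read_catch_csv: 0 rows read, 0 rows rejected")
    return(empty_catch_records())
  }
  line <- seq_len(nrow(raw)) + 1L # header occupies line 1

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(date)) {
    stop("unparseable ISO-8601 date on line(s): ",
         paste(line[is.na(date)], collapse = ", "))
  }
  trap <- normalize_trap(raw$trap)
  bad_trap <- !(trap %in% trap_codes)
  if (any(bad_trap)) {
    stop("unknown trap code(s) ", paste(unique(raw$trap[bad_trap]), collapse = ", "),
         " on line(s): ", paste(line[bad_trap], collapse = ", "),
         " (known codes: ", paste(trap_codes, collapse = ", "), ")")
  }
  count <- suppressWarnings(as.numeric(raw$count))
  bad_count <- is.na(count) | count < 0 | count != round(count)
  if (any(bad_count)) {
    stop("count must be a non-negative integer; invalid on line(s): ",
         paste(line[bad_count], collapse = ", "))
  }
  hour_chr <- trimws(raw$hour)
  hour <- suppressWarnings(as.integer(hour_chr))
  has_hour <- !is.na(hour_chr) & nzchar(hour_chr)
  bad_hour <- has_hour & (is.na(hour) | !(hour %in% valid_hours))
  if (any(bad_hour)) {
    stop("hour must be an integer in 18-23 or 0-5; invalid on line(s): ",
         paste(line[bad_hour], collapse = ", "))
  }
  hour[!has_hour] <- NA_integer_

  out <- data.frame(date = date, village = raw$village, trap = trap,
                    taxon = raw$taxon, hour = hour,
                    count = as.integer(count), stringsAsFactors = FALSE)
  class(out) <- c("catch_records", "data.frame")
  message("read_catch_csv: ", nrow(out), " rows read, 0 rows rejected")
  out
}

empty_catch_records <- function() {
  out <- data.frame(date = as.Date(character()), village = character(),
                    trap = character(), taxon = character(),
                    hour = integer(), count = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("catch_records", "data.frame")
  out
}

#' Write trap-night records back to the standard catch CSV schema
#'
#' @param records A `"catch_records"` data frame (see [read_catch_csv()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catch_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- as.data.frame(records)[, c("date", "village", "trap", "taxon", "hour", "count")]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pool hourly collections into one record per trap-night
#'
#' Collapses hourly rows to a single nightly count per
#' (date, village, trap, taxon) key, summing counts and clearing the hour
#' field. Already-nightly rows (hour absent) pass through unchanged, which
#' makes the operation idempotent. A key holding a nightly row alongside any
#' other row (a double entry) is ambiguous and raises an error.
#'
#' @param records A `"catch_records"` data frame, possibly mixing hourly and
#'   nightly rows.
#' @return A `"catch_records"` data frame with one row per key and `hour`
#'   set to `NA`, ordered by date, village, trap and taxon.
#' @export
pool_hourly <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(empty_catch_records())
  key <- paste(records$date, records$village, records$trap, records$taxon,
               sep = "\r")
  nightly <- is.na(records$hour)
  n_night <- tapply(nightly, key, sum)
  n_rows <- tapply(nightly, key, length)
  dup <- names(n_night)[n_night > 1 | (n_night == 1 & n_rows > 1)]
  if (length(dup) > 0) {
    parts <- strsplit(dup[1], "\r", fixed = TRUE)[[1]]
    stop("ambiguous double entry: nightly row duplicated for (",
         paste(parts, collapse = ", "), ")",
         if (length(dup) > 1) paste0(" and ", length(dup) - 1, " other key(s)"))
  }
  agg <- aggregate(count ~ date + village + trap + taxon,
                   data = as.data.frame(records), FUN = sum)
  agg <- agg[order(agg$date, agg$village, agg$trap, agg$taxon), ]
  out <- data.frame(date = agg$date, village = agg$village, trap = agg$trap,
                    taxon = agg$taxon, hour = NA_integer_,
                    count = as.integer(agg$count), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("catch_records", "data.frame")
  out
}

#' Construct an aligned per-night catch table
#'
#' Builds the container the models consume: per night, the HLC count `N`,
#' the focal alternative-trap count `n`, the pooled other-taxa count `m`
#' caught in the same trap, and the per-taxon components `s` of `m`.
#'
#' @param night_id Character identifiers, one per night. Defaults to
#'   `night_1, night_2, ...`.
#' @param N Non-negative integer vector: HLC counts of the focal taxon.
#' @param n Non-negative integer vector: focal-trap counts of the focal taxon.
#' @param m Optional non-negative integer vector: pooled other-taxa counts.
#'   Computed as `rowSums(s)` when `s` is given; defaults to all zero.
#' @param s Optional matrix (nights x K) of per-taxon other-group counts.
#'   When both `m` and `s` are supplied, `m` must equal the row sums of `s`.
#' @param taxon,trap Optional labels carried along for reporting.
#' @param other_taxa Optional character vector naming the columns of `s`.
#' @return An object of class `"catch_table"`: a list with elements
#'   `night_id`, `N`, `n`, `m`, `s`, `K`, `taxon`, `trap`, `other_taxa`.
#' @seealso [build_catch_table()] to assemble one from records.
#' @export
catch_table <- function(night_id = NULL, N, n, m = NULL, s = NULL,
                        taxon = NA_character_, trap = NA_character_,
                        other_taxa = NULL) {
  N <- as.integer(N)
  n <- as.integer(n)
  nights <- length(N)
  if (length(n) != nights) stop("N and n must have a common length")
  if (is.null(night_id)) {
    night_id <- if (nights == 0) character(0) else paste0("night_", seq_len(nights))
  }
  if (length(night_id) != nights) stop("night_id length must match N")
  if (!is.null(s)) {
    s <- as.matrix(s)
    storage.mode(s) <- "integer"
    if (nrow(s) != nights) stop("s must have one row per night")
    if (is.null(other_taxa)) {
      other_taxa <- colnames(s)
      if (is.null(other_taxa)) other_taxa <- paste0("taxon_", seq_len(ncol(s)))
    }
    colnames(s) <- other_taxa
    if (is.null(m)) m <- rowSums(s)
  } else {
    s <- matrix(integer(), nrow = nights, ncol = 0)
    other_taxa <- character()
    if (is.null(m)) m <- integer(nights)
  }
  m <- as.integer(m)
  if (length(m) != nights) stop("m length must match N")
  counts <- c(N, n, m, as.vector(s))
  if (anyNA(counts) || any(counts < 0)) {
    stop("all counts must be non-negative integers")
  }
  if (ncol(s) > 0 && !all(m == rowSums(s))) {
    stop("m must equal the per-night sum of s")
  }
  structure(list(night_id = as.character(night_id), N = N, n = n, m = m,
                 s = s, K = ncol(s), taxon = taxon, trap = trap,
                 other_taxa = other_taxa),
            class = "catch_table")
}

#' @export
print.catch_table <- function(x, ...) {
  cat("Catch table:", length(x$N), "nights",
      if (!is.na(x$trap)) paste0("(", x$trap, " vs HLC)"), "\n")
  if (!is.na(x$taxon)) cat("  focal taxon:", x$taxon, "\n")
  cat("  HLC total:", sum(x$N), "  trap total:", sum(x$n),
      "  other-taxa groups (K):", x$K, "\n")
  if (x$K > 0) cat("  other taxa:", paste(x$other_taxa, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.catch_table <- function(x, ...) {
  out <- data.frame(night_id = x$night_id, N = x$N, n = x$n, m = x$m,
                    stringsAsFactors = FALSE)
  if (x$K > 0) {
    s <- as.data.frame(x$s)
    names(s) <- paste0("s_", x$other_taxa)
    out <- cbind(out, s)
  }
  out
}

#' Subset a catch table by night
#'
#' @param x A `"catch_table"`.
#' @param i Night indices (integer or logical).
#' @param ... Unused.
#' @return A `"catch_table"` restricted to the selected nights.
#' @export
`[.catch_table` <- function(x, i, ...) {
  catch_table(night_id = x$night_id[i], N = x$N[i], n = x$n[i], m = x$m[i],
              s = if (x$K > 0) x$s[i, , drop = FALSE] else NULL,
              taxon = x$taxon, trap = x$trap,
              other_taxa = if (x$K > 0) x$other_taxa else NULL)
}

#' @export
length.catch_table <- function(x) length(x$N)

#' Assemble a catch table from nightly records
#'
#' Aligns HLC and a focal alternative trap night by night, keyed on
#' (date, village). Nights lacking a record from either method are dropped
#' with a logged count; within retained nights a missing taxon row is a zero
#' catch. `m` is the per-night sum of the `other_taxa` counts in the focal
#' trap, with the per-taxon components kept in `s`.
#'
#' @param records Nightly `"catch_records"` (run [pool_hourly()] first if
#'   hourly rows are present).
#' @param focal_taxon Taxon label whose HLC counts form the response.
#' @param trap Focal alternative trap code (see [trap_codes]).
#' @param other_taxa Character vector of other taxon labels contributing to
#'   `m`. Defaults to every other taxon observed in the focal trap's records.
#' @return A `"catch_table"` (see [catch_table()]).
#' @export
build_catch_table <- function(records, focal_taxon, trap, other_taxa = NULL) {
  stopifnot(is.data.frame(records))
  if (any(!is.na(records$hour))) {
    stop("records contain hourly rows; run pool_hourly() first")
  }
  trap <- normalize_trap(trap)
  if (!(trap %in% trap_codes) || trap == "HLC") {
    stop("trap must be one of ", paste(setdiff(trap_codes, "HLC"), collapse = ", "))
  }
  night <- paste(records$date, records$village, sep = "\r")
  nights_hlc <- unique(night[records$trap == "HLC"])
  nights_alt <- unique(night[records$trap == trap])
  keep <- intersect(nights_hlc, nights_alt)
  n_dropped <- length(union(nights_hlc, nights_alt)) - length(keep)
  if (length(keep) == 0) {
    stop("no overlapping nights between HLC and ", trap)
  }
  if (n_dropped > 0) {
    message("build_catch_table: dropped ", n_dropped,
            " night(s) lacking either HLC or ", trap)
  }
  keep <- keep[order(keep)]

  if (is.null(other_taxa)) {
    other_taxa <- sort(setdiff(unique(records$taxon[records$trap == trap]),
                               focal_taxon))
  }
  if (focal_taxon %in% other_taxa) {
    stop("focal taxon '", focal_taxon, "' must not appear in other_taxa")
  }

  counts_for <- function(trap_code, taxon) {
    sel <- records$trap == trap_code & records$taxon == taxon
    v <- setNames(integer(length(keep)), keep)
    if (any(sel)) {
      got <- tapply(records$count[sel], night[sel], sum)
      got <- got[names(got) %in% keep]
      v[names(got)] <- as.integer(got)
    }
    v
  }

  N <- counts_for("HLC", focal_taxon)
  n <- counts_for(trap, focal_taxon)
  s <- if (length(other_taxa) > 0) {
    vapply(other_taxa, function(tx) counts_for(trap, tx), integer(length(keep)))
  } else NULL
  if (!is.null(s)) s <- matrix(s, nrow = length(keep),
                               dimnames = list(NULL, other_taxa))
  night_id <- gsub("\r", "/", keep, fixed = TRUE)
  catch_table(night_id = night_id, N = unname(N), n = unname(n), s = s,
              taxon = focal_taxon, trap = trap,
              other_taxa = if (!is.null(s)) other_taxa else NULL)
}
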