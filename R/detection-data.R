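#' Construct a detection history object
#'
#' @param y binary site x occasion matrix (`NA` = camera inactive).
#' @param site_ids site labels (default rownames of `y`).
#' @param species species label.
#' @param occasion_dates optional vector of first dates per occasion.
#' @return an object of class `"detection_history"`.
#' @export
detection_history <- function(y, site_ids = rownames(y), species = NA_character_,
                              occasion_dates = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  if (!all(y[!is.na(y)] %in% c(0, 1))) stop("detection history must be binary (0/1/NA)")
  if (is.null(site_ids)) site_ids <- sprintf("S%03d", seq_len(nrow(y)))
  rownames(y) <- site_ids
  structure(list(y = y, site_ids = site_ids, species = species,
                 occasion_dates = occasion_dates),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  cat(sprintf("Detection history for %s: %d sites x %d occasions, %d detections, naive occupancy %.3f\n",
              x$species, nrow(x$y), ncol(x$y), sum(x$y == 1, na.rm = TRUE),
              mean(rowSums(x$y == 1, na.rm = TRUE) > 0)))
  invisible(x)
}

#' Read a camera-trap record table
#'
#' Reads a CSV with columns `site_id`, `species`, `datetime` (ISO-8601 or
#' `"%Y-%m-%d %H:%M:%S"`), `count`, and optionally `burst_id`, and parses
#' the timestamps. Timestamps are taken as local clock time (no daylight
#' saving arithmetic).
#'
#' @param path CSV file path.
#' @return data.frame of records with a parsed `datetime` column (`POSIXct`).
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "species", "datetime", "count")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("records file lacks columns: ", paste(miss, collapse = ", "))
  rec$datetime <- parse_datetime(rec$datetime)
  rec
}

## tolerant ISO-8601 / space-separated timestamp parser (local clock time)
parse_datetime <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  d_only <- is.na(out) & !is.na(x)
  out[d_only] <- as.POSIXct(x[d_only], tz = "UTC", format = "%Y-%m-%d")
  out
}

#' Collapse photo bursts into detection events
#'
#' Cameras record a fixed burst of (typically three) photos per trigger;
#' for analysis each burst is one detection event. Rows are grouped by
#' `(site_id, species, burst_id)` when a `burst_id` column is present;
#' otherwise consecutive same-site same-species photos separated by at most
#' `gap` seconds form one event. The event time is the first photo's time
#' and the event count is the maximum per-photo count in the burst. Rows
#' with unparseable timestamps are dropped with a warning; the number
#' dropped is stored in attribute `"n_rejected"`.
#'
#' @param records record data.frame (see [read_records()]).
#' @param gap burst gap rule in seconds when `burst_id` is absent
#'   (default 30).
#' @return data.frame of events: `site_id`, `species`, `datetime`, `count`,
#'   `n_photos`, `burst_id`.
#' @export
collapse_bursts <- function(records, gap = 30) {
  records$datetime <- parse_datetime(records$datetime)
  bad <- is.na(records$datetime)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unparseable datetime dropped")
    records <- records[!bad, , drop = FALSE]
  }
  empty <- data.frame(site_id = character(), species = character(),
                      datetime = as.POSIXct(character(), tz = "UTC"),
                      count = numeric(), n_photos = integer(),
                      burst_id = character())
  attr(empty, "n_rejected") <- sum(bad)
  if (nrow(records) == 0) return(empty)
  ord <- order(records$site_id, records$species, records$datetime)
  records <- records[ord, , drop = FALSE]
  if (!is.null(records$burst_id) && !anyNA(records$burst_id)) {
    key <- paste(records$site_id, records$species, records$burst_id, sep = "\r")
  } else {
    dt <- as.numeric(records$datetime)
    new_run <- c(TRUE, records$site_id[-1] != records$site_id[-nrow(records)] |
                   records$species[-1] != records$species[-nrow(records)] |
                   diff(dt) > gap)
    key <- paste(records$site_id, records$species, cumsum(new_run), sep = "\r")
  }
  first <- !duplicated(key)
  cnt <- tapply(records$count, key, max)
  nph <- tapply(records$count, key, length)
  ev <- records[first, c("site_id", "species", "datetime"), drop = FALSE]
  k <- key[first]
  ev$count <- as.numeric(cnt[k])
  ev$n_photos <- as.integer(nph[k])
  ev$burst_id <- if (!is.null(records$burst_id)) records$burst_id[first]
                 else vapply(strsplit(k, "\r"), `[`, character(1), 3)
  ev <- ev[order(ev$site_id, ev$species, ev$datetime), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "n_rejected") <- sum(bad)
  ev
}

#' Build a site-by-occasion detection history
#'
#' Divides the study period into consecutive occasions of `occasion_days`
#' days starting at the earliest camera start date, sets `y[i, j] = 1` when
#' the site has at least one event of the species within occasion `j`, and
#' masks (sets `NA`) occasions entirely outside a camera's active range.
#'
#' @param events event table from [collapse_bursts()].
#' @param species focal species label.
#' @param effort data.frame `site_id`, `start`, `end` (`Date` or parseable)
#'   giving each camera's active range; defines the site order and universe.
#' @param occasion_days occasion length in days (>= 1, default 1).
#' @return a `detection_history` whose rows follow `effort$site_id`.
#' @export
build_history <- function(events, species, effort, occasion_days = 1) {
  stopifnot(occasion_days >= 1)
  effort$start <- as.Date(effort$start); effort$end <- as.Date(effort$end)
  ev <- events[events$species == species, , drop = FALSE]
  unknown <- setdiff(unique(ev$site_id), effort$site_id)
  if (length(unknown))
    stop("event(s) at site(s) absent from the effort table: ",
         paste(unknown, collapse = ", "))
  origin <- min(effort$start)
  n_days <- as.integer(max(effort$end) - origin) + 1L
  J <- ceiling(n_days / occasion_days)
  n <- nrow(effort)
  y <- matrix(0, n, J, dimnames = list(effort$site_id, NULL))
  # mask occasions with no overlap with the camera's active range
  occ_start <- origin + (seq_len(J) - 1) * occasion_days
  occ_end <- occ_start + occasion_days - 1
  for (i in seq_len(n)) {
    off <- occ_end < effort$start[i] | occ_start > effort$end[i]
    y[i, off] <- NA
  }
  if (nrow(ev)) {
    day <- as.integer(as.Date(ev$datetime) - origin)
    occ <- day %/% occasion_days + 1L
    inside <- occ >= 1 & occ <= J
    for (e in which(inside)) y[ev$site_id[e], occ[e]] <- 1
  }
  dates <- occ_start
  detection_history(y, effort$site_id, species, occasion_dates = dates)
}

#' Photo-level count covariate per site
#'
#' Sums the `count` field over all photos (not collapsed events) whose
#' species belongs to a group — e.g. the total number of humans observed
#' across all photos at a camera, or livestock (cattle or oxen, domestic
#' buffalo and goats).
#'
#' @param records photo-level record data.frame.
#' @param species_group character vector of species labels in the group.
#' @param sites optional site universe; sites with no matching photos get 0.
#' @return named numeric vector of per-site totals.
#' @export
count_covariate <- function(records, species_group, sites = NULL) {
  if (is.null(sites)) sites <- sort(unique(records$site_id))
  out <- stats::setNames(numeric(length(sites)), sites)
  sel <- records$species %in% species_group
  if (any(sel)) {
    tot <- tapply(records$count[sel], records$site_id[sel], sum)
    tot <- tot[names(tot) %in% sites]
    out[names(tot)] <- as.numeric(tot)
  }
  out
}

#' Extract a diel activity sample from events
#'
#' Converts the clock times of one species' detection events to radian time
#' of day. With `mode = "hourly"` at most one event per site-hour is kept,
#' thinning bursts of repeat triggers; the default uses all events.
#'
#' @param events event table from [collapse_bursts()].
#' @param species focal species label.
#' @param mode `"all"` (default) or `"hourly"`.
#' @return numeric vector of radian times in `[0, 2*pi)`.
#' @export
diel_sample <- function(events, species, mode = c("all", "hourly")) {
  mode <- match.arg(mode)
  ev <- events[events$species == species, , drop = FALSE]
  if (mode == "hourly" && nrow(ev)) {
    hr <- format(ev$datetime, "%Y-%m-%d %H")
    ev <- ev[!duplicated(paste(ev$site_id, hr)), , drop = FALSE]
  }
  to_radians(ev$datetime)
}
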