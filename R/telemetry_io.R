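## Tabular I/O for the four study inputs. All timestamps are stored as POSIXct
## in UTC; CSV files use ISO-8601 timestamps, a header row and comma separators.

parse_utc <- function(x, what = "timestamp") {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  iso_t <- grepl("T", x, fixed = TRUE)
  if (any(iso_t)) {
    out[iso_t] <- as.POSIXct(sub("Z$", "", x[iso_t]),
                             format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  if (any(!iso_t)) {
    out[!iso_t] <- tryCatch(
      as.POSIXct(x[!iso_t], tz = "UTC",
                 tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")),
      error = function(e) as.POSIXct(NA, tz = "UTC"))
  }
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("unparseable %s at row(s) %s (first value: '%s')",
                 what, paste(head(bad, 5L), collapse = ", "), x[bad[1L]]),
         call. = FALSE)
  }
  out
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read a detection table
#'
#' Columns: `tag_id`, `receiver_id`, `timestamp` (ISO-8601, UTC). Exact
#' duplicate rows (same tag, receiver and instant) are removed with a message;
#' near-duplicates are kept. Rows are sorted by (tag_id, timestamp).
#'
#' @param path CSV file path.
#' @return data frame of detections with POSIXct UTC timestamps; the number of
#'   duplicates dropped is attached as attribute `n_duplicates`.
#' @export
read_detections <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("tag_id", "receiver_id", "timestamp"), "detections")
  df$tag_id <- as.character(df$tag_id)
  df$receiver_id <- as.character(df$receiver_id)
  if (any(!nzchar(df$tag_id)) || any(!nzchar(df$receiver_id))) {
    stop("detections: empty tag_id or receiver_id", call. = FALSE)
  }
  df$timestamp <- parse_utc(df$timestamp)
  if (anyNA(df$timestamp)) stop("detections: missing timestamp", call. = FALSE)
  as_detections(df[c("tag_id", "receiver_id", "timestamp")])
}

## Canonicalize: dedup exact (tag, receiver, instant) triples, sort, count.
as_detections <- function(df) {
  key <- paste(df$tag_id, df$receiver_id, as.numeric(df$timestamp), sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0L) {
    message(sprintf("removed %d duplicate detection(s)", n_dup))
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$tag_id, df$timestamp, df$receiver_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_duplicates") <- n_dup
  df
}

#' Read a receiver station table
#'
#' Columns: `receiver_id`, `chainage_km` and optionally `x`, `y`,
#' `active_from`, `active_to`.
#'
#' @param path CSV file path.
#' @return data frame of stations.
#' @export
read_receivers <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("receiver_id", "chainage_km"), "receivers")
  df$receiver_id <- as.character(df$receiver_id)
  validate_receivers(df)
  if ("active_from" %in% names(df)) df$active_from <- parse_utc(df$active_from, "active_from")
  if ("active_to" %in% names(df)) df$active_to <- parse_utc(df$active_to, "active_to")
  if (all(c("active_from", "active_to") %in% names(df))) {
    both <- !is.na(df$active_from) & !is.na(df$active_to)
    if (any(both & df$active_from[both] >= df$active_to[both])) {
      stop("receivers: active_from must precede active_to", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

validate_receivers <- function(df) {
  if (any(is.na(df$chainage_km)) || any(df$chainage_km < 0)) {
    stop("receivers: chainage_km must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(df$receiver_id)) {
    stop("receivers: duplicated receiver_id", call. = FALSE)
  }
  invisible(df)
}

#' Read an individual metadata table
#'
#' Columns: `individual_id`, `sex` (male/female/unknown), `total_length_m`.
#'
#' @param path CSV file path.
#' @return data frame of individuals.
#' @export
read_individuals <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("individual_id", "sex", "total_length_m"), "individuals")
  df$individual_id <- as.character(df$individual_id)
  df$sex <- as.character(df$sex)
  bad_sex <- !(df$sex %in% c("male", "female", "unknown"))
  if (any(bad_sex)) {
    stop(sprintf("individuals: invalid sex value '%s'", df$sex[which(bad_sex)[1L]]),
         call. = FALSE)
  }
  if (any(is.na(df$total_length_m)) || any(df$total_length_m <= 0)) {
    stop("individuals: total_length_m must be positive", call. = FALSE)
  }
  df
}

#' Construct a river axis
#'
#' A river axis is the channel centreline: ordered planar vertices with the
#' cumulative along-channel distance (chainage, km) at each vertex. When only
#' a chainage map is available the axis is represented as a straight line.
#'
#' @param x data frame with columns `x`, `y` (planar km) or a numeric vector /
#'   one-column frame of chainage breakpoints.
#' @return object of class `river_axis` with elements `x`, `y`, `chainage_km`.
#' @export
river_axis <- function(x) {
  if (is.numeric(x)) x <- data.frame(chainage_km = x)
  if (all(c("x", "y") %in% names(x))) {
    seg <- sqrt(diff(x$x)^2 + diff(x$y)^2)
    ch <- c(0, cumsum(seg))
    ax <- list(x = x$x, y = x$y, chainage_km = ch)
  } else if ("chainage_km" %in% names(x)) {
    ch <- sort(unique(as.numeric(x$chainage_km)))
    ax <- list(x = ch, y = rep(0, length(ch)), chainage_km = ch)
  } else {
    stop("river axis needs columns x,y or chainage_km", call. = FALSE)
  }
  if (length(ax$chainage_km) < 2L || any(diff(ax$chainage_km) <= 0)) {
    stop("river axis chainage must be strictly increasing with total length > 0",
         call. = FALSE)
  }
  class(ax) <- "river_axis"
  ax
}

#' Read a river axis from CSV or GeoJSON
#'
#' Accepts a CSV of ordered vertices (`vertex_index`, `x`, `y`), a CSV
#' chainage map (`chainage_km`), or a GeoJSON file whose first feature (or
#' bare geometry) is a LineString in planar km coordinates.
#'
#' @param path file path (.csv, .json or .geojson).
#' @return a [river_axis()] object.
#' @export
read_river_axis <- function(path) {
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path, simplifyVector = TRUE)
    coords <- if (!is.null(gj$coordinates)) gj$coordinates
      else if (!is.null(gj$features)) gj$features$geometry$coordinates[[1L]]
      else if (!is.null(gj$geometry)) gj$geometry$coordinates
      else stop("GeoJSON: no LineString coordinates found", call. = FALSE)
    coords <- as.matrix(coords)
    return(river_axis(data.frame(x = coords[, 1L], y = coords[, 2L])))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("vertex_index" %in% names(df)) df <- df[order(df$vertex_index), , drop = FALSE]
  river_axis(df)
}

#' Load a full study
#'
#' Reads and validates the four input tables.
#'
#' @param paths named list/vector with entries `detections`, `receivers`,
#'   `river`, `individuals`.
#' @param config optional [study_config()]; unused for reading but recorded.
#' @return list with elements `detections`, `receivers`, `river_axis`,
#'   `individuals`.
#' @export
load_study <- function(paths, config = study_config()) {
  for (nm in c("detections", "receivers", "river", "individuals")) {
    if (is.null(paths[[nm]])) stop(sprintf("paths$%s is required", nm), call. = FALSE)
    if (!file.exists(paths[[nm]])) stop(sprintf("file not found: %s", paths[[nm]]), call. = FALSE)
  }
  list(detections = read_detections(paths[["detections"]]),
       receivers = read_receivers(paths[["receivers"]]),
       river_axis = read_river_axis(paths[["river"]]),
       individuals = read_individuals(paths[["individuals"]]))
}

#' Cross-validate the loaded collections
#'
#' Flags (never drops) detections that reference unknown receivers or tags and
#' detections outside their receiver's deployment interval, and tabulates
#' per-individual detection counts.
#'
#' @param detections,receivers,individuals loaded tables.
#' @return list with `orphan_receiver_rows`, `unknown_tag_rows`,
#'   `out_of_deployment_rows` (integer row indices into `detections`) and
#'   `detection_counts` (data frame individual_id, n_detections).
#' @export
validate_study <- function(detections, receivers, individuals) {
  orphan <- which(!(detections$receiver_id %in% receivers$receiver_id))
  unknown_tag <- which(!(detections$tag_id %in% individuals$individual_id))
  out_dep <- integer(0)
  if (any(c("active_from", "active_to") %in% names(receivers))) {
    i <- match(detections$receiver_id, receivers$receiver_id)
    from <- if ("active_from" %in% names(receivers)) receivers$active_from[i] else NA
    to <- if ("active_to" %in% names(receivers)) receivers$active_to[i] else NA
    before <- !is.na(from) & detections$timestamp < from
    after <- !is.na(to) & detections$timestamp > to
    out_dep <- which((before | after) & !is.na(i))
  }
  counts <- as.data.frame(table(tag_id = detections$tag_id), stringsAsFactors = FALSE)
  names(counts) <- c("individual_id", "n_detections")
  list(orphan_receiver_rows = orphan,
       unknown_tag_rows = unknown_tag,
       out_of_deployment_rows = out_dep,
       detection_counts = counts)
}

format_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write result tables with a manifest
#'
#' Each table is written as a headered CSV; timestamps are serialized as
#' ISO-8601 UTC. A `manifest.json` records file names, row counts and the
#' configuration hash.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @param config configuration list hashed into the manifest.
#' @return the manifest, invisibly.
#' @export
write_outputs <- function(tables, out_dir, config = list()) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  files <- character(0)
  rows <- integer(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    for (col in names(df)) {
      if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_utc(df[[col]])
    }
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(df, f, row.names = FALSE)
    files <- c(files, basename(f))
    rows <- c(rows, nrow(df))
  }
  manifest <- list(files = files, rows = rows, config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write study input tables
#'
#' Serializes synthetic (or cleaned) study inputs in the same schemas that
#' [load_study()] reads, so a write/read cycle is lossless.
#'
#' @param study list as returned by [load_study()] or [simulate_detections()].
#' @param dir output directory.
#' @return named vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  det <- study$detections
  det$timestamp <- format_utc(det$timestamp)
  rec <- study$receivers
  for (col in c("active_from", "active_to")) {
    if (col %in% names(rec)) rec[[col]] <- format_utc(rec[[col]])
  }
  ax <- study$river_axis
  axis_df <- data.frame(vertex_index = seq_along(ax$x), x = ax$x, y = ax$y)
  paths <- c(detections = file.path(dir, "detections.csv"),
             receivers = file.path(dir, "receivers.csv"),
             river = file.path(dir, "river.csv"),
             individuals = file.path(dir, "individuals.csv"))
  write.csv(det, paths[["detections"]], row.names = FALSE)
  write.csv(rec, paths[["receivers"]], row.names = FALSE)
  write.csv(axis_df, paths[["river"]], row.names = FALSE)
  write.csv(study$individuals, paths[["individuals"]], row.names = FALSE)
  invisible(paths)
}
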