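#' Read and write track CSV files
#'
#' Tracks travel as CSV with header `track_id,t,x,y` (`t` in MCS or model
#' steps, `x`/`y` in pixels, unwrapped across the periodic boundary).
#' Reading validates the header, rejects malformed rows with their line
#' numbers, and enforces strictly increasing, uniformly spaced times
#' within each track.
#'
#' @param tracks Data frame with `track_id`, `t`, `x`, `y`.
#' @param path File path.
#' @return `read_tracks()` returns the validated data frame;
#'   `write_tracks()` returns `path` invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(all(c("track_id", "t", "x", "y") %in% names(tracks)))
  write.csv(tracks[, c("track_id", "t", "x", "y")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  if (!identical(header, c("track_id", "t", "x", "y"))) {
    stop("expected header 'track_id,t,x,y' in ", path)
  }
  tracks <- read.csv(path, colClasses = c("integer", rep("numeric", 3)))
  bad <- which(!stats::complete.cases(tracks))
  if (length(bad) > 0) {
    stop("malformed rows in ", path, " at line(s) ",
         paste(bad + 1, collapse = ", "))
  }
  for (tr in split(tracks, tracks$track_id)) {
    if (nrow(tr) < 2) next
    dt <- diff(tr$t)
    if (any(dt <= 0) || any(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1))) {
      stop("track ", tr$track_id[1],
           ": times must be strictly increasing with constant spacing")
    }
  }
  tracks
}

#' Write and read plain-text lattice snapshots
#'
#' One grid row (`y`) per line, cell ids space-separated. Only the
#' identity layer is stored; reading returns the integer matrix (indexed
#' `[x, y]` like `cpm_state$identity`).
#'
#' @param state A `cpm_state`.
#' @param path File path.
#' @return `read_grid()` returns the identity matrix; `write_grid()`
#'   returns `path` invisibly.
#' @export
write_grid <- function(state, path) {
  lines <- apply(state$identity, 2, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  rows <- lapply(strsplit(readLines(path), " "), as.integer)
  n <- lengths(rows)
  if (length(unique(n)) != 1) stop("ragged grid file: ", path)
  matrix(unlist(rows), nrow = n[1], ncol = length(rows))
}

#' Write evolution history CSV
#'
#' Columns `run, generation, individual, parent, <parameters...>,
#' sim_seed, fitness, broken, annihilated, survivor`.
#'
#' @param history An `evolution_history` (or list of them; each gets its
#'   own `run` number).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  if (inherits(history, "evolution_history")) history <- list(history)
  rows <- lapply(seq_along(history), function(i) {
    h <- history[[i]]$history
    cbind(run = i, h)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit with the same
#' build: the command, full configuration, master seed, package version,
#' timestamp and output file inventory.
#'
#' @param path Manifest path.
#' @param command Command or function name.
#' @param config Configuration list (coerced to JSON).
#' @param seed Master seed.
#' @param files Character vector of output files.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, files = character()) {
  config <- config[!vapply(config, is.function, TRUE)]
  manifest <- list(
    command = command,
    config = config,
    master_seed = seed,
    package = "actevolve",
    version = as.character(utils::packageVersion("actevolve")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = files)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE, digits = NA)
  invisible(path)
}
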