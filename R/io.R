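#' Integrated data bundle
#'
#' Collects the three observation sets and their shared spatial frame.  All
#' coordinates are kilometres in one local planar frame; files produced from
#' projected (UTM) metres should be divided by 1000 and offset to a local
#' origin before or during import.
#'
#' @param traps Live [trap_array()].
#' @param scr [scr_data()] matching `traps`.
#' @param cameras Camera [trap_array()] (optional).
#' @param occ [occ_data()] matching `cameras` (optional).
#' @param telemetry [telemetry_data()] linked to `scr` rows (optional).
#' @param space [state_space()]; built from the arrays with a 2 km buffer
#'   when missing.
#' @return A `scrim_data` object.
#' @export
scrim_data <- function(traps, scr, cameras = NULL, occ = NULL,
                       telemetry = NULL, space = NULL) {
  stopifnot(inherits(traps, "trap_array"), traps$kind == "live",
            inherits(scr, "scr_data"))
  if (ncol(scr$y) != n_traps(traps)) stop("scr columns != number of live traps")
  if (!is.null(occ)) {
    stopifnot(inherits(cameras, "trap_array"), cameras$kind == "camera",
              inherits(occ, "occ_data"))
    if (length(occ$counts) != n_traps(cameras))
      stop("occ counts != number of cameras")
  }
  if (!is.null(telemetry)) {
    stopifnot(inherits(telemetry, "telemetry_data"))
    if (any(telemetry$link > nrow(scr$y)))
      stop("telemetry links to an individual absent from the capture data")
  }
  arrays <- c(list(traps), if (!is.null(cameras)) list(cameras))
  if (is.null(space)) space <- state_space_from_arrays(arrays, 2)
  inside <- function(a)
    all(a$coords[, 1] >= space$xlim[1], a$coords[, 1] <= space$xlim[2],
        a$coords[, 2] >= space$ylim[1], a$coords[, 2] <= space$ylim[2])
  if (!all(vapply(arrays, inside, logical(1))))
    stop("detector envelope extends outside the state space")
  structure(list(traps = traps, cameras = cameras, scr = scr, occ = occ,
                 telemetry = telemetry, space = space),
            class = "scrim_data")
}

#' @export
print.scrim_data <- function(x, ...) {
  cat(sprintf("integrated SCR bundle: %d individuals, %d captures, %d live traps\n",
              nrow(x$scr$y), sum(x$scr$y), n_traps(x$traps)))
  if (!is.null(x$occ))
    cat(sprintf("  occupancy: %d cameras, %d detections\n",
                n_traps(x$cameras), sum(x$occ$counts)))
  if (!is.null(x$telemetry))
    cat(sprintf("  telemetry: %d tagged, %s fixes\n",
                length(x$telemetry$fixes),
                paste(vapply(x$telemetry$fixes, nrow, 1L), collapse = "/")))
  print(x$space)
  invisible(x)
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty input file: ", path)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  df
}

#' Read a detector file
#'
#' CSV columns: `trap_id, x_km, y_km, kind, K` and optionally `bait` (0/1,
#' live traps only).  `kind` must be constant within a file (`live` or
#' `camera`).
#'
#' @param path CSV path.
#' @return A [trap_array()]; trap ids kept as the attribute `ids`.
#' @export
read_traps <- function(path) {
  df <- read_csv_checked(path, c("trap_id", "x_km", "y_km", "kind", "K"))
  if (anyDuplicated(df$trap_id)) stop("duplicate trap_id in ", path)
  if (!is.numeric(df$x_km) || !is.numeric(df$y_km))
    stop("non-numeric coordinates in ", path)
  kind <- unique(df$kind)
  if (length(kind) != 1L || !kind %in% c("live", "camera"))
    stop("kind must be a single value, 'live' or 'camera'")
  if (any(df$K < 0)) stop("negative effort K in ", path)
  bait <- NULL
  if ("bait" %in% names(df) && kind == "live") {
    if (!all(df$bait %in% c(0, 1))) stop("bait values must be 0 or 1")
    bait <- df$bait
  }
  out <- trap_array(cbind(df$x_km, df$y_km), kind, df$K, bait)
  attr(out, "ids") <- as.character(df$trap_id)
  out
}

#' Read SCR captures
#'
#' Long CSV `individual_id, trap_id, count`; pivoted to an n x J count
#' matrix with individuals ordered by first appearance.
#'
#' @param path CSV path.
#' @param traps Live [trap_array()] from [read_traps()] (needs `ids`).
#' @return An [scr_data()].
#' @export
read_captures <- function(path, traps) {
  df <- read_csv_checked(path, c("individual_id", "trap_id", "count"))
  ids <- attr(traps, "ids")
  if (is.null(ids)) ids <- as.character(seq_len(n_traps(traps)))
  jj <- match(as.character(df$trap_id), ids)
  if (anyNA(jj)) stop("unknown trap_id: ",
                      paste(unique(df$trap_id[is.na(jj)]), collapse = ", "))
  indiv <- unique(as.character(df$individual_id))
  y <- matrix(0L, length(indiv), n_traps(traps))
  ii <- match(as.character(df$individual_id), indiv)
  for (r in seq_len(nrow(df))) y[ii[r], jj[r]] <- y[ii[r], jj[r]] + df$count[r]
  bad <- which(sweep(y, 2L, traps$effort) > 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("count exceeds effort K for individual '%s' at trap '%s'",
                 indiv[bad[1, 1]], ids[bad[1, 2]]))
  scr_data(y, traps, individuals = indiv)
}

#' Read occupancy detections
#'
#' CSV `camera_id, detections`, one row per camera.
#'
#' @param path CSV path.
#' @param cameras Camera [trap_array()] with `ids`.
#' @return An [occ_data()].
#' @export
read_occ <- function(path, cameras) {
  df <- read_csv_checked(path, c("camera_id", "detections"))
  ids <- attr(cameras, "ids")
  if (is.null(ids)) ids <- as.character(seq_len(n_traps(cameras)))
  jj <- match(as.character(df$camera_id), ids)
  if (anyNA(jj)) stop("unknown camera_id in ", path)
  counts <- rep(0L, n_traps(cameras))
  counts[jj] <- as.integer(df$detections)
  occ_data(counts, cameras)
}

#' Read telemetry fixes
#'
#' CSV `individual_id, day, x_km, y_km`.  Individuals must appear in the
#' capture data (tagged animals come from the capture cohort).  Duplicate
#' individual-days are rejected unless `thin = TRUE`, in which case one fix
#' per day is kept at random.
#'
#' @param path CSV path.
#' @param scr [scr_data()] providing the individual ordering.
#' @param thin Apply [thin_telemetry()] to duplicate days.
#' @param seed Seed for thinning.
#' @return A [telemetry_data()].
#' @export
read_telemetry <- function(path, scr, thin = FALSE, seed = NULL) {
  df <- read_csv_checked(path, c("individual_id", "day", "x_km", "y_km"))
  names(df)[names(df) == "individual_id"] <- "individual"
  names(df)[names(df) == "x_km"] <- "x"
  names(df)[names(df) == "y_km"] <- "y"
  dup <- anyDuplicated(df[c("individual", "day")]) > 0
  if (dup && !thin)
    stop("duplicate individual-day fixes; re-run with thin = TRUE")
  if (thin) df <- thin_telemetry(df, seed)
  link <- match(unique(df$individual), scr$individuals)
  if (anyNA(link))
    stop("telemetry individual(s) not present in capture data: ",
         paste(unique(df$individual)[is.na(link)], collapse = ", "))
  fixes <- lapply(split(df[c("x", "y")], factor(df$individual,
                                                unique(df$individual))),
                  as.matrix)
  telemetry_data(unname(fixes), link)
}

#' Write a bundle to CSV files
#'
#' Writes `traps.csv`, `cameras.csv`, `captures.csv`, `occ.csv`,
#' `telemetry.csv` (as present) and `space.json` under `dir`, in the
#' dialects the readers accept.
#'
#' @param bundle A [scrim_data()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the vector of file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wt <- function(traps, file, prefix) {
    ids <- attr(traps, "ids")
    if (is.null(ids)) ids <- paste0(prefix, seq_len(n_traps(traps)))
    df <- data.frame(trap_id = ids, x_km = traps$coords[, 1],
                     y_km = traps$coords[, 2], kind = traps$kind,
                     K = traps$effort)
    if (!is.null(traps$bait)) df$bait <- traps$bait
    utils::write.csv(df, file, row.names = FALSE)
    ids
  }
  tf <- file.path(dir, "traps.csv")
  trap_ids <- wt(bundle$traps, tf, "T"); paths <- c(paths, tf)
  idx <- which(bundle$scr$y > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]  # first-appearance order
  cap <- data.frame(individual_id = bundle$scr$individuals[idx[, 1]],
                    trap_id = trap_ids[idx[, 2]],
                    count = bundle$scr$y[idx])
  cf <- file.path(dir, "captures.csv")
  utils::write.csv(cap, cf, row.names = FALSE); paths <- c(paths, cf)
  if (!is.null(bundle$occ)) {
    camf <- file.path(dir, "cameras.csv")
    cam_ids <- wt(bundle$cameras, camf, "C")
    of <- file.path(dir, "occ.csv")
    utils::write.csv(data.frame(camera_id = cam_ids,
                                detections = bundle$occ$counts),
                     of, row.names = FALSE)
    paths <- c(paths, camf, of)
  }
  if (!is.null(bundle$telemetry)) {
    tel <- bundle$telemetry
    rows <- do.call(rbind, lapply(seq_along(tel$fixes), function(i) {
      f <- tel$fixes[[i]]
      data.frame(individual_id = bundle$scr$individuals[tel$link[i]],
                 day = seq_len(nrow(f)), x_km = f[, 1], y_km = f[, 2])
    }))
    telf <- file.path(dir, "telemetry.csv")
    utils::write.csv(rows, telf, row.names = FALSE); paths <- c(paths, telf)
  }
  sf <- file.path(dir, "space.json")
  jsonlite::write_json(list(xlim = bundle$space$xlim,
                            ylim = bundle$space$ylim), sf,
                       auto_unbox = FALSE, digits = NA)
  paths <- c(paths, sf)
  invisible(paths)
}

#' Read a bundle from CSV files
#'
#' Inverse of [write_bundle()].
#'
#' @param dir Directory holding the files.
#' @return A [scrim_data()].
#' @export
read_bundle <- function(dir) {
  traps <- read_traps(file.path(dir, "traps.csv"))
  scr <- read_captures(file.path(dir, "captures.csv"), traps)
  cameras <- occ <- tel <- NULL
  if (file.exists(file.path(dir, "cameras.csv"))) {
    cameras <- read_traps(file.path(dir, "cameras.csv"))
    occ <- read_occ(file.path(dir, "occ.csv"), cameras)
  }
  if (file.exists(file.path(dir, "telemetry.csv")))
    tel <- read_telemetry(file.path(dir, "telemetry.csv"), scr)
  space <- NULL
  sj <- file.path(dir, "space.json")
  if (file.exists(sj)) {
    sp <- jsonlite::read_json(sj, simplifyVector = TRUE)
    space <- state_space(sp$xlim, sp$ylim)
  }
  scrim_data(traps = traps, cameras = cameras, scr = scr, occ = occ,
             telemetry = tel, space = space)
}

#' Load a fit or scenario configuration from JSON
#'
#' Unknown keys are rejected (typo safety); known keys override the
#' documented defaults of [fit_config()] / [scenario_config()].
#'
#' @param path JSON file.
#' @param kind `"fit"` or `"scenario"`.
#' @return A `fit_config` or `scenario_config`.
#' @export
load_config <- function(path, kind = c("fit", "scenario")) {
  kind <- match.arg(kind)
  vals <- if (file.exists(path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else stop("config file not found: ", path)
  target <- if (kind == "fit") fit_config else scenario_config
  known <- names(formals(target))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(known, collapse = ", "))
  do.call(target, vals)
}
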