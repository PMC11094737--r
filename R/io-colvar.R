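# COLVAR-style pulling tables: whitespace-delimited columns with a
# `#! FIELDS <names...>` header line (PLUMED dialect). Units on file are
# nm for distances and kJ mol^-1 nm^-1 for the bias force; forces are
# converted to pN on read.

#' Write a COLVAR-style pulling table
#'
#' @param df data.frame with columns `time` (ns), `distance` (nm), `center`
#'   (nm) and optionally `bias` (kJ mol^-1 nm^-1).
#' @param path output file.
#' @param fields column names to write after `#! FIELDS` (defaults to
#'   time, d1, restraint.center, restraint.bias).
#' @return `path`, invisibly.
#' @export
write_colvar <- function(df, path,
                         fields = c("time", "d1", "restraint.center",
                                    "restraint.bias")) {
  cols <- intersect(c("time", "distance", "center", "bias"), names(df))
  fields <- fields[seq_along(cols)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(fields, collapse = " ")), con)
  utils::write.table(format(df[, cols], digits = 12, trim = TRUE,
                            scientific = FALSE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a COLVAR-style pulling table
#'
#' Parses a whitespace table with a `#! FIELDS` header. Mandatory columns:
#' time and a distance collective variable (first field starting with `d`
#' or named `distance`). A restraint-center column (`*cntr*`/`*center*`)
#' and a bias-force column (`*bias*`/`*force*`) are used when present.
#' Restart-duplicated time blocks are deduplicated keeping the later block.
#'
#' @param path file path.
#' @return data.frame with columns `time` (ns), `distance` (nm) and, when
#'   present, `center` (nm) and `bias` (kJ mol^-1 nm^-1).
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) stop("cannot read COLVAR file: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  if (!grepl("^#!\\s*FIELDS", header))
    stop(path, ": missing '#! FIELDS' header line", call. = FALSE)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", header), "\\s+")[[1]]
  df <- utils::read.table(path, comment.char = "#", col.names = fields,
                          check.names = FALSE)
  pick <- function(pattern) {
    hit <- grep(pattern, fields, value = TRUE, ignore.case = TRUE)
    if (length(hit)) hit[1] else NA_character_
  }
  tcol <- pick("^time$")
  dcol <- pick("^(d[0-9]*|distance)$")
  if (is.na(tcol) || is.na(dcol))
    stop(path, ": mandatory columns (time, distance) not found", call. = FALSE)
  out <- data.frame(time = df[[tcol]], distance = df[[dcol]])
  ccol <- pick("cntr|center")
  bcol <- pick("bias|force")
  if (!is.na(ccol)) out$center <- df[[ccol]]
  if (!is.na(bcol)) out$bias <- df[[bcol]]
  dedup_restarts(out)
}

# Keep the later block wherever a restart rewound the time stamps.
dedup_restarts <- function(df) {
  t <- df$time
  keep <- rep(TRUE, length(t))
  last_t <- -Inf
  # scan from the end: later blocks win; earlier rows with time >= the
  # minimum of any later block are dropped
  min_later <- Inf
  for (i in rev(seq_along(t))) {
    if (t[i] >= min_later) keep[i] <- FALSE else min_later <- t[i]
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a pulling series as a force series
#'
#' Reads a COLVAR-style table and returns a `"force_series"` in internal
#' units (force in pN). If the file has a bias-force column it is converted
#' directly; otherwise the spring force is reconstructed from the schedule
#' (warning). If the restraint-center column is absent it is computed from
#' the schedule.
#'
#' @param path COLVAR-style file.
#' @param schedule optional [pulling_schedule()]; required when the file
#'   lacks a bias column.
#' @return a `"force_series"` data.frame: `time`, `distance`, `center`,
#'   `force_pN`.
#' @export
read_pull_series <- function(path, schedule = NULL) {
  df <- read_colvar(path)
  if (is.null(df$center)) {
    if (is.null(schedule))
      stop(path, ": no restraint-center column and no schedule given",
           call. = FALSE)
    df$center <- restraint_center(schedule, df$time)
  }
  if (!is.null(df$bias)) {
    out <- data.frame(time = df$time, distance = df$distance,
                      center = df$center, force_pN = df$bias * KJMOL_NM_TO_PN)
  } else {
    if (is.null(schedule))
      stop(path, ": no bias-force column and no schedule to reconstruct from",
           call. = FALSE)
    warning("no bias column; reconstructing spring force from the schedule",
            call. = FALSE)
    out <- as.data.frame(spring_force(df$time, df$distance, schedule,
                                      center = df$center))
  }
  structure(out, class = c("force_series", "data.frame"))
}
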