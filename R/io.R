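## Plain-text interchange: one CSV per site (time_ms, u1..u4 at full float64
## precision) plus a JSON sidecar carrying geometry, labels, sampling rate,
## a config echo and the seed. CSVs are written at %.17g so a write/read
## round trip is bit-exact.

.fmtNum <- function(x) sprintf("%.17g", x)

.configToList <- function(config) {
  nms <- slotNames(config)
  stats::setNames(lapply(nms, function(s) slot(config, s)), nms)
}

.listToConfig <- function(lst) {
  do.call(synthConfig, lst)
}

## Polynomial rolling hash of the config JSON, 8 hex digits; provenance
## stamp for output files.
.configHash <- function(config) {
  s <- jsonlite::toJSON(.configToList(config), auto_unbox = TRUE, digits = I(17))
  h <- 17
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a cohort to a directory
#'
#' One `<site_id>.csv` per site with columns `time_ms, u1, u2, u3, u4`
#' (full float64 precision) and a `cohort.json` sidecar with electrode
#' coordinates, sampling rate, labels, the simulator configuration echo and
#' its seed.
#'
#' @param cohort list with `recordings` and `labels` as from
#'   [simulateCohort()]
#' @param dir output directory (created if absent)
#' @param config optional [SynthConfig-class] echoed into the sidecar
#' @return `dir`, invisibly
#' @export
writeCohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    n <- nrow(rec@signals)
    tMs <- (seq_len(n) - 1L) / rec@fs * 1000
    df <- data.frame(time_ms = .fmtNum(tMs),
                     u1 = .fmtNum(rec@signals[, 1]),
                     u2 = .fmtNum(rec@signals[, 2]),
                     u3 = .fmtNum(rec@signals[, 3]),
                     u4 = .fmtNum(rec@signals[, 4]))
    data.table::fwrite(df, file.path(dir, paste0(rec@siteId, ".csv")),
                       quote = FALSE)
  }
  side <- list(
    fs = cohort$recordings[[1]]@fs,
    coords = unname(cohort$recordings[[1]]@coords),
    labels = cohort$labels,
    sites = vapply(cohort$recordings, siteId, character(1))
  )
  if (!is.null(config)) {
    side$config <- .configToList(config)
    side$seed <- config@seed
    side$config_hash <- .configHash(config)
  }
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE),
             file.path(dir, "cohort.json"))
  invisible(dir)
}

#' Read a cohort directory
#'
#' Inverse of [writeCohort()]; checks per-file structure and the
#' consistency of the CSV time axis with the sidecar's sampling rate.
#'
#' @param dir directory written by [writeCohort()]
#' @return list with `recordings`, `labels`, and (when echoed) `config`
#' @export
readCohort <- function(dir) {
  sideFile <- file.path(dir, "cohort.json")
  if (!file.exists(sideFile)) stop("no cohort.json sidecar in ", dir)
  side <- jsonlite::fromJSON(sideFile, simplifyVector = TRUE)
  fs <- as.numeric(side$fs)
  xy <- matrix(as.numeric(side$coords), ncol = 2,
               dimnames = list(paste0("e", seq_len(nrow(side$coords))),
                               c("x", "y")))
  recs <- lapply(side$sites, function(id) {
    f <- file.path(dir, paste0(id, ".csv"))
    if (!file.exists(f)) stop("missing site file ", f)
    df <- data.table::fread(f, colClasses = "numeric", showProgress = FALSE)
    need <- c("time_ms", "u1", "u2", "u3", "u4")
    if (!identical(names(df), need))
      stop("malformed header in ", f, " (need ", paste(need, collapse = ","), ")")
    bad <- which(!stats::complete.cases(df))
    if (length(bad))
      stop("parse error in ", f, ": incomplete record at data line ", bad[1])
    dt <- diff(df$time_ms)
    if (max(abs(dt - 1000 / fs)) > 1e-6 * 1000 / fs)
      stop("sampling-rate mismatch in ", f, ": sidecar fs = ", fs,
           " Hz does not match the CSV time axis")
    cliqueRecording(as.matrix(df[, c("u1", "u2", "u3", "u4")]), xy, fs, id)
  })
  names(recs) <- side$sites
  out <- list(recordings = recs, labels = as.data.frame(side$labels))
  if (!is.null(side$config)) out$config <- .listToConfig(side$config)
  out
}

#' Write / read site annotations
#'
#' Full-precision CSV with columns `site_id, V_bi, V_omni, PF_bi, PF_omni`.
#'
#' @param ann annotations data.frame from [annotateCohort()]
#' @param path CSV path
#' @return `path` (write) or the annotations data.frame (read)
#' @export
writeAnnotations <- function(ann, path) {
  df <- data.frame(site_id = ann$site_id,
                   V_bi = .fmtNum(ann$V_bi), V_omni = .fmtNum(ann$V_omni),
                   PF_bi = .fmtNum(ann$PF_bi), PF_omni = .fmtNum(ann$PF_omni))
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  df <- data.table::fread(path, showProgress = FALSE)
  need <- c("site_id", "V_bi", "V_omni", "PF_bi", "PF_omni")
  if (!identical(names(df), need))
    stop("malformed annotation header in ", path)
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop("parse error in ", path, ": incomplete record at data line ", bad[1])
  as.data.frame(df)
}
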