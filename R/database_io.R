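## Beam-database persistence: one CSV per (ion, energy) plus a JSON manifest.
## Numeric columns are written at full precision so a write/read round trip
## reproduces every table bit-exactly.

.fmt_full <- function(x) {
  s <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", s)
}

#' Write a beam database to disk
#'
#' Layout: `manifest.json` describing ions, energies, the FWHM-in-air,
#' range-shifter-widening and HU-calibration tables, plus one CSV per
#' (ion, energy) with columns `depth_mm, idd, s1, s2, s3, w1, w2, w3, let_d,
#' alpha, beta, zstar`.
#'
#' @param db a `beam_db`.
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_beam_database <- function(db, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (ion in names(db$ions)) {
    slot <- db$ions[[ion]]
    for (key in names(slot$entries)) {
      e <- slot$entries[[key]]
      fn <- sprintf("%s_%sMeV.csv", ion, key)
      df <- data.frame(depth_mm = .fmt_full(e$depths))
      for (cn in .TABLE_COLS) df[[cn]] <- .fmt_full(e$table[, cn])
      write.csv(df, file.path(path, fn), row.names = FALSE, quote = FALSE)
      files[[length(files) + 1]] <- list(ion = ion, energy = e$energy,
                                         file = fn)
    }
  }
  manifest <- list(
    format_version = "1.0",
    depth_step = db$depth_step,
    rs_reference_wet = db$rs_reference_wet,
    seed = db$seed,
    ions = lapply(db$ions, function(s) s$energies),
    files = files,
    fwhm_air = db$fwhm_air,
    rs_widening = db$rs_widening,
    hu_calibration = db$hu_calibration
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a beam database from disk
#'
#' Inverse of [write_beam_database()]; validates every table on load and
#' reports the offending file and row on failure.
#'
#' @param path directory containing `manifest.json`.
#' @return a `beam_db`.
#' @export
read_beam_database <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  ions <- list()
  for (i in seq_len(nrow(manifest$files))) {
    rec <- manifest$files[i, ]
    f <- file.path(path, rec$file)
    if (!file.exists(f))
      stop(sprintf("manifest references missing file '%s'", rec$file))
    df <- read.csv(f)
    need <- c("depth_mm", .TABLE_COLS)
    if (!all(need %in% names(df)))
      stop(sprintf("%s: missing columns %s", rec$file,
                   paste(setdiff(need, names(df)), collapse = ", ")))
    tab <- as.matrix(df[.TABLE_COLS])
    entry <- list(ion = rec$ion, energy = rec$energy, depths = df$depth_mm,
                  table = tab,
                  peak_depth = df$depth_mm[which.max(tab[, "idd"])])
    if (is.null(ions[[rec$ion]]))
      ions[[rec$ion]] <- list(energies = numeric(0), entries = list())
    ions[[rec$ion]]$energies <- c(ions[[rec$ion]]$energies, rec$energy)
    ions[[rec$ion]]$entries[[.energy_key(rec$energy)]] <- entry
  }
  for (ion in names(ions)) {
    o <- order(ions[[ion]]$energies)
    ions[[ion]]$energies <- ions[[ion]]$energies[o]
    ions[[ion]]$entries <- ions[[ion]]$entries[o]
  }
  db <- list(ions = ions,
             fwhm_air = as.data.frame(manifest$fwhm_air),
             rs_widening = as.data.frame(manifest$rs_widening),
             hu_calibration = as.data.frame(manifest$hu_calibration),
             rs_reference_wet = manifest$rs_reference_wet,
             depth_step = manifest$depth_step,
             seed = manifest$seed)
  class(db) <- "beam_db"
  validate_beam_database(db, context = path)
  db
}
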