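# Delimited-text interchange: one long-format CSV per record plus one JSON
# sidecar per dataset. Numbers are written with 17 significant digits so a
# write -> read round trip reproduces doubles bit-exactly.

fmt_num <- function(x) formatC(x, digits = 17, format = "g", width = -1)

write_record_csv <- function(path, header, cols) {
  lines <- c(paste(header, collapse = ","),
             do.call(paste, c(lapply(cols, fmt_num), sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
}

sidecar_meta <- function(meta, file, qf = NA_real_) {
  out <- list(file = file, head_id = meta$head_id, tissue = meta$tissue,
              prep_method = meta$prep_method, replicate = meta$replicate,
              exposure_time_s = meta$exposure_time_s,
              laser_power_mw = meta$laser_power_mw)
  if (!is.na(qf)) out$qf <- qf
  out
}

#' Write a dataset to a directory
#'
#' Writes one `shift_cm1,intensity` CSV per processed record (or a
#' `pixel,dark,frame_*` CSV per raw record) plus a `dataset.json` sidecar
#' carrying the axis, per-record metadata and provenance (including the
#' generator seed when present). Output is deterministic: two writes of the
#' same dataset are byte-identical.
#'
#' @param ds A [raman_set()] or [raman_raw_set()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    abort_io(sprintf("cannot create directory '%s'", path))
  if (file.access(path, 2) != 0)
    abort_io(sprintf("directory '%s' is not writable", path))

  if (inherits(ds, "raman_set")) {
    keys <- rownames(ds$meta)
    ord <- order(keys)
    records <- lapply(ord, function(i) {
      f <- paste0(keys[i], ".csv")
      write_record_csv(file.path(path, f), c("shift_cm1", "intensity"),
                       list(ds$axis$shifts, ds$spectra[i, ]))
      m <- as.list(ds$meta[i, ])
      sidecar_meta(structure(m, class = "acquisition_meta"), f, m$qf)
    })
    side <- list(schema = "processed",
                 axis = list(shifts = ds$axis$shifts,
                             nominal_resolution = ds$axis$nominal_resolution),
                 provenance = ds$provenance, records = records)
  } else if (inherits(ds, "raman_raw_set")) {
    keys <- names(ds$acquisitions)
    ord <- order(keys)
    records <- lapply(ord, function(i) {
      a <- ds$acquisitions[[i]]
      f <- paste0(keys[i], ".csv")
      nf <- nrow(a$frames)
      cols <- c(list(seq_len(a$axis_pixels), a$dark_frame),
                lapply(seq_len(nf), function(j) a$frames[j, ]))
      write_record_csv(file.path(path, f),
                       c("pixel", "dark", sprintf("frame_%02d", seq_len(nf))),
                       cols)
      c(sidecar_meta(a$meta, f), list(saturation = a$saturation))
    })
    side <- list(schema = "raw", provenance = ds$provenance, records = records)
  } else abort_schema("ds must be a raman_set or raman_raw_set")

  json <- jsonlite::toJSON(side, auto_unbox = TRUE, digits = I(17), null = "null")
  con <- file(file.path(path, "dataset.json"), open = "wb")
  writeLines(json, con = con, sep = "\n")
  close(con)
  invisible(path)
}

require_field <- function(rec, field, where) {
  if (is.null(rec[[field]]))
    abort_schema(sprintf("metadata field '%s' missing in %s", field, where))
  rec[[field]]
}

#' Read a dataset written by [write_dataset()]
#'
#' All structural invariants are validated on load: the closed tissue
#' vocabulary, axis/intensity length agreement, unique record keys and (for
#' processed data) the per-spectrum SNV contract.
#'
#' @param path Directory containing `dataset.json` and the record CSVs.
#' @param schema `"processed"` or `"raw"`; must match the sidecar.
#' @return A [raman_set()] or [raman_raw_set()].
#' @export
read_dataset <- function(path, schema = c("processed", "raw")) {
  schema <- match.arg(schema)
  sidefile <- file.path(path, "dataset.json")
  if (!file.exists(sidefile))
    abort_io(sprintf("no dataset.json sidecar under '%s'", path))
  side <- jsonlite::fromJSON(sidefile, simplifyVector = FALSE)
  if (is.null(side$schema) || side$schema != schema)
    abort_schema(sprintf("sidecar schema '%s' does not match requested '%s'",
                         side$schema, schema))
  prov <- side$provenance
  if (is.null(prov)) prov <- list()

  metas <- lapply(seq_along(side$records), function(i) {
    rec <- side$records[[i]]
    where <- sprintf("record %d", i)
    acquisition_meta(
      head_id = require_field(rec, "head_id", where),
      tissue = require_field(rec, "tissue", where),
      prep_method = require_field(rec, "prep_method", where),
      exposure_time_s = require_field(rec, "exposure_time_s", where),
      laser_power_mw = require_field(rec, "laser_power_mw", where),
      replicate = require_field(rec, "replicate", where))
  })

  if (schema == "processed") {
    shifts <- as.numeric(unlist(side$axis$shifts))
    nres <- if (is.null(side$axis$nominal_resolution)) 8.7 else
      side$axis$nominal_resolution
    if (!length(side$records)) {
      ax <- if (length(shifts)) spectral_axis(shifts, nres) else
        spectral_axis(c(800, 1800), nres)
      return(raman_set(ax, matrix(numeric(0), 0, length(ax$shifts)),
                       meta_as_row(acquisition_meta(1, "pituitary_gland"))[0, ],
                       provenance = prov))
    }
    rows <- vector("list", length(side$records))
    qfs <- numeric(length(side$records))
    for (i in seq_along(side$records)) {
      rec <- side$records[[i]]
      tab <- utils::read.csv(file.path(path, require_field(rec, "file", "record")),
                             colClasses = "numeric")
      if (nrow(tab) != length(shifts))
        abort_structural(sprintf(
          "record '%s': %d intensity rows but axis has %d bins",
          rec$file, nrow(tab), length(shifts)))
      if (max(abs(tab$shift_cm1 - shifts)) > 1e-6)
        abort_structural(sprintf("record '%s': shifts disagree with sidecar axis",
                                 rec$file))
      rows[[i]] <- tab$intensity
      qfs[i] <- if (is.null(rec$qf)) NA_real_ else rec$qf
    }
    meta <- do.call(rbind, lapply(seq_along(metas), function(i)
      meta_as_row(metas[[i]], qfs[i])))
    raman_set(spectral_axis(shifts, nres), do.call(rbind, rows), meta,
              provenance = prov)
  } else {
    acqs <- lapply(seq_along(side$records), function(i) {
      rec <- side$records[[i]]
      tab <- utils::read.csv(file.path(path, require_field(rec, "file", "record")),
                             colClasses = "numeric")
      fcols <- grep("^frame_", names(tab), value = TRUE)
      frames <- unname(t(as.matrix(tab[, fcols, drop = FALSE])))
      sat <- if (is.null(rec$saturation)) 65535 else rec$saturation
      if (length(tab$dark) != ncol(frames))
        abort_structural(sprintf("record '%s': dark frame length mismatch",
                                 rec$file))
      raw_acquisition(frames, tab$dark, metas[[i]], saturation = sat)
    })
    raman_raw_set(acqs, provenance = prov)
  }
}
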