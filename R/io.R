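#' Write a recording as a BrainVision triplet
#'
#' Produces `<base>.vhdr` (text header), `<base>.vmrk` (text markers) and
#' `<base>.eeg` (IEEE float32, multiplexed) next to each other. Marker
#' positions are written 1-based per the format convention; event payloads
#' go into the marker description field.
#'
#' @param rec an [new_recording()].
#' @param base path prefix (without extension).
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, base) {
  name <- basename(base)
  vhdr <- paste0(base, ".vhdr")
  vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", name, ".eeg"),
    paste0("MarkerFile=", name, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    paste0("Ch", seq_len(nrow(rec$data)), "=", rec$montage$label, ",,1,uV")
  )
  writeLines(hdr, vhdr)
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", name, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  )
  if (nrow(rec$events)) {
    mk <- c(mk, paste0("Mk", seq_len(nrow(rec$events)) + 1L, "=",
                       rec$events$kind, ",", rec$events$payload, ",",
                       rec$events$sample + 1L, ",1,0"))
  }
  writeLines(mk, vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  invisible(vhdr)
}

#' Read a BrainVision triplet
#'
#' Minimal reader for the files this package writes (multiplexed IEEE
#' float32). Positions are not part of the format; supply the montage used
#' at write time, or a placeholder spiral layout is built from the channel
#' labels.
#'
#' @param vhdr path to the `.vhdr` header.
#' @param montage optional montage data.frame matching the channel labels.
#' @return an [new_recording()].
#' @export
read_brainvision <- function(vhdr, montage = NULL) {
  lines <- readLines(vhdr)
  get_val <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)[1L]
    sub(paste0("^", key, "="), "", ln)
  }
  n_ch <- as.integer(get_val("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_val("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[[`, "", 1L)
  dir <- dirname(vhdr)
  eeg <- file.path(dir, get_val("DataFile"))
  vmrk <- file.path(dir, get_val("MarkerFile"))
  sz <- file.info(eeg)$size
  n_samp <- as.integer(sz / 4L / n_ch)
  con <- file(eeg, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n_ch * n_samp, size = 4L,
                 endian = "little")
  data <- matrix(raw, nrow = n_ch)
  mlines <- grep("^Mk[0-9]+=", readLines(vmrk), value = TRUE)
  ev <- do.call(rbind, lapply(strsplit(sub("^Mk[0-9]+=", "", mlines), ","),
                              function(p) {
    data.frame(sample = as.integer(p[3L]) - 1L, kind = p[1L],
               payload = if (length(p) >= 2L) p[2L] else "",
               stringsAsFactors = FALSE)
  }))
  ev <- ev[ev$kind != "New Segment", , drop = FALSE]
  if (is.null(montage)) {
    montage <- build_montage(max(16L, n_ch))[seq_len(n_ch), ]
    montage$label <- labels
  }
  new_recording(data, fs, montage, ev)
}

#' Write / read a long band-power table as TSV
#' @param x band-power data.frame.
#' @param path file path.
#' @export
write_band_power <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_band_power
#' @export
read_band_power <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("band_power_table", "data.frame")
  out
}

#' Write a ground-truth bundle as JSON
#' @param gt list of per-subject ground-truth entries.
#' @param path file path.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
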