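#' Write a session to disk (EDF + hypnogram CSV)
#'
#' Stores the 4-contact voltages as `lfp.edf` (one EDF signal per contact)
#' and the hypnogram as `hypnogram.csv` with header `epoch,onset_s,stage`
#' (stages serialized as `W,N1,N2,N3,R`), inside directory `path`.
#'
#' @param session An `lfp_session`.
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "lfp_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  edf_write(session$contacts, session$fs, file.path(path, "lfp.edf"),
            labels = colnames(session$contacts),
            patient_id = session$subject_id)
  hyp <- data.frame(epoch = seq_along(session$hypnogram$stages) - 1L,
                    onset_s = (seq_along(session$hypnogram$stages) - 1L) * 30L,
                    stage = session$hypnogram$stages)
  utils::write.csv(hyp, file.path(path, "hypnogram.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a session from disk
#'
#' Loads `lfp.edf` and `hypnogram.csv` from a directory written by
#' [write_session()], validating that the recording has exactly 4 contacts,
#' that all stage labels are legal, and that the EDF duration matches the
#' hypnogram (one 30-s epoch per 30 s of signal).
#'
#' @param path Directory containing `lfp.edf` and `hypnogram.csv`.
#' @param subject_id Optional subject id override; default the EDF patient
#'   field.
#' @return An `lfp_session`.
#' @export
read_session <- function(path, subject_id = NULL) {
  edf_path <- file.path(path, "lfp.edf")
  csv_path <- file.path(path, "hypnogram.csv")
  if (!file.exists(edf_path) || !file.exists(csv_path))
    stop("session directory must contain lfp.edf and hypnogram.csv")
  edf <- edf_read(edf_path)
  if (ncol(edf$signals) != 4)
    stop(sprintf("expected 4 DBS contacts, found %d EDF channels",
                 ncol(edf$signals)))
  hyp <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (!all(c("epoch", "onset_s", "stage") %in% names(hyp)))
    stop("hypnogram.csv must have columns epoch,onset_s,stage")
  bad <- setdiff(unique(hyp$stage), sleep_stages())
  if (length(bad))
    stop(sprintf("hypnogram.csv contains unknown stage label(s): %s",
                 paste(bad, collapse = ", ")))
  if (abs(edf$duration_s - 30 * nrow(hyp)) > 1e-9)
    stop(sprintf(
      "EDF duration (%g s) does not match hypnogram (%d epochs = %g s)",
      edf$duration_s, nrow(hyp), 30 * nrow(hyp)))
  if (is.null(subject_id)) {
    con <- file(edf_path, "rb")
    readBin(con, "raw", 8)
    subject_id <- trimws(rawToChar(readBin(con, "raw", 80)))
    close(con)
  }
  structure(list(subject_id = subject_id, fs = edf$fs,
                 contacts = edf$signals,
                 hypnogram = hypnogram(hyp$stage)),
            class = "lfp_session")
}
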