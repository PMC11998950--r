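#' Sample record and record store
#'
#' Mirrors the app's internal sample database: each saved measurement keeps
#' the sample id, the sex label (pass-through metadata, never used in any
#' computation), the reported hematocrit, the three marker rows it was
#' computed from, the capture pose if known, and the image path. The store
#' backend is a single human-readable CSV file.
#'
#' @param sample_id Unique text id.
#' @param sex Pass-through text label (may be `NA`).
#' @param markers A [marker_set()]; the stored `hct_pct` is computed from it.
#' @param pose Optional [camera_pose()].
#' @param image_path Optional path to the saved image.
#' @param app_version Text version tag.
#' @param created_at Timestamp (default now, UTC).
#' @return A `sample_record` (one-row tibble).
#' @export
sample_record <- function(sample_id, markers, sex = NA_character_,
                          pose = NULL, image_path = NA_character_,
                          app_version = "microhct 0.1.0",
                          created_at = format(Sys.time(), tz = "UTC",
                                              "%Y-%m-%dT%H:%M:%SZ")) {
  stopifnot(inherits(markers, "marker_set"))
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id)) {
    stop_microhct("`sample_id` must be a non-empty string.", "microhct_invalid_record")
  }
  hct <- compute_hct(markers)
  out <- tibble::tibble(
    sample_id = sample_id, sex = as.character(sex),
    hct_pct = hct$hct_pct,
    lower = markers$lower_row, buffy = markers$buffy_row,
    upper = markers$upper_row,
    pitch = if (is.null(pose)) NA_real_ else pose$pitch_deg,
    yaw = if (is.null(pose)) NA_real_ else pose$yaw_deg,
    roll = if (is.null(pose)) NA_real_ else pose$roll_deg,
    height_cm = if (is.null(pose)) NA_real_ else pose$height_cm,
    setback_cm = if (is.null(pose)) NA_real_ else pose$setback_cm,
    image_path = as.character(image_path),
    created_at = created_at, app_version = app_version
  )
  class(out) <- c("sample_record", class(out))
  out
}

#' Open (or create) a record store
#'
#' @param path Path of the backing CSV file; created empty if absent.
#' @return A `record_store` handle.
#' @export
record_store <- function(path) {
  if (!file.exists(path)) {
    write.csv(empty_store_df(), path, row.names = FALSE)
  }
  structure(list(path = path), class = "record_store")
}

empty_store_df <- function() {
  sample_record("placeholder", marker_set(2, 1.5, 1))[0, ]
}

#' Save a record into a store
#'
#' @param store A [record_store()].
#' @param record A [sample_record()].
#' @return The stored sample id, invisibly. Duplicate ids are a conflict
#'   error.
#' @export
save_record <- function(store, record) {
  stopifnot(inherits(store, "record_store"), inherits(record, "sample_record"))
  existing <- load_records(store, revalidate = FALSE)
  if (record$sample_id %in% existing$sample_id) {
    stop_microhct(sprintf("Record '%s' already exists in the store.",
                          record$sample_id),
                  "microhct_conflict")
  }
  out <- dplyr::bind_rows(existing, record)
  write.csv(out, store$path, row.names = FALSE)
  invisible(record$sample_id)
}

#' Load all records from a store
#'
#' On load each record's stored hematocrit is revalidated against its marker
#' rows; a disagreement beyond the 0.1-point reporting precision raises an
#' integrity warning (the record is still returned).
#'
#' @param store A [record_store()].
#' @param revalidate Recompute and check `hct_pct` from the marker columns.
#' @return Tibble of records (possibly empty).
#' @export
load_records <- function(store, revalidate = TRUE) {
  stopifnot(inherits(store, "record_store"))
  df <- tibble::as_tibble(read.csv(store$path, colClasses = c(
    sample_id = "character", sex = "character", image_path = "character",
    created_at = "character", app_version = "character")))
  if (revalidate && nrow(df) > 0) {
    recomputed <- vapply(seq_len(nrow(df)), function(i) {
      compute_hct(marker_set(df$lower[i], df$buffy[i], df$upper[i]))$hct_pct
    }, numeric(1))
    bad <- abs(recomputed - df$hct_pct) > 0.1 + 1e-9
    if (any(bad)) {
      warn(sprintf(
        "Stored hematocrit disagrees with markers for record(s): %s",
        paste(df$sample_id[bad], collapse = ", ")),
        class = "microhct_integrity_warning")
    }
  }
  df
}

#' Export a store as a spreadsheet-compatible table
#'
#' Column order: `sample_id, sex, hct_pct, lower, buffy, upper, pitch, yaw,
#' image_path, created_at`. Re-importing the written CSV yields the same
#' table.
#'
#' @param store A [record_store()].
#' @param path Optional CSV path to write.
#' @return The export tibble.
#' @export
export_table <- function(store, path = NULL) {
  df <- load_records(store, revalidate = FALSE)
  if (nrow(df) == 0) {
    stop_microhct("The store is empty; nothing to export.",
                  "microhct_empty_export")
  }
  out <- df[, c("sample_id", "sex", "hct_pct", "lower", "buffy", "upper",
                "pitch", "yaw", "image_path", "created_at")]
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
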