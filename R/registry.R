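#' Device calibration registry
#'
#' The registry maps the device IDs found in crowdsensed entries (the
#' platform's verbatim build-model constants, e.g. `"SM-G930F"`) to a
#' canonical model name and, where available, a calibration profile. Alias
#' groups collect several device IDs under one model name (e.g. the
#' `"Moto G"` group spans `"Moto G"`, `"XT1028"` and `"XT1032"`), so all
#' members share the model's calibration. Matching is case-sensitive exact
#' string comparison.
#'
#' `default_registry()` returns the packaged registry: the five
#' experimentally calibrated profiles plus the uncalibrated device-ID to
#' model-name mappings for the most common devices in the platform
#' database.
#'
#' @param path Path to a registry JSON file: an array of records
#'   `{device_id, model_name, aliases, slope, intercept, r_squared,
#'   source}` with `slope`/`intercept` null for uncalibrated mappings.
#' @return A tibble with one row per device ID (aliases expanded), columns
#'   `device_id`, `model_name`, `canonical_id` (the group's primary ID),
#'   `slope`, `intercept`, `r_squared`, `source`, and `calibrated`
#'   (logical).
#' @examples
#' reg <- default_registry()
#' dplyr::filter(reg, calibrated)
#' @export
read_registry <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- purrr::map_dfr(recs, function(r) {
    ids <- unique(c(r$device_id, unlist(r$aliases)))
    tibble::tibble(
      device_id = ids,
      model_name = r$model_name,
      canonical_id = r$device_id,
      slope = if (is.null(r$slope)) NA_real_ else as.numeric(r$slope),
      intercept = if (is.null(r$intercept)) NA_real_ else as.numeric(r$intercept),
      r_squared = if (is.null(r$r_squared)) NA_real_ else as.numeric(r$r_squared),
      source = if (is.null(r$source)) "registry" else r$source
    )
  })
  if (anyDuplicated(rows$device_id)) {
    dup <- unique(rows$device_id[duplicated(rows$device_id)])
    stop("duplicate device IDs in registry: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(rows, calibrated = is.finite(slope) & is.finite(intercept))
}

#' @rdname read_registry
#' @export
default_registry <- function() {
  read_registry(system.file("extdata", "device_registry.json",
                            package = "crowdnoise", mustWork = TRUE))
}

#' Resolve a device ID against the registry
#'
#' Looks a device ID up by exact match first, then (as a fallback) by
#' canonical model name, so `"XT1028"` and `"Galaxy S7"` both resolve.
#' Unknown IDs are a normal outcome: they resolve to model `"unknown"`
#' with no calibration.
#'
#' @param device_id Character vector of device IDs.
#' @param registry Registry tibble from [read_registry()] /
#'   [default_registry()].
#' @return A tibble with one row per input ID: `device_id`, `model_name`,
#'   `canonical_id` (the alias group's primary device ID), `slope`,
#'   `intercept`, `r_squared`, `calibrated`.
#' @examples
#' resolve_device(c("SM-G930F", "XT1028", "NONEXISTENT-ID"))
#' @export
resolve_device <- function(device_id, registry = default_registry()) {
  idx <- match(device_id, registry$device_id)
  # fallback: an ID that is itself a canonical model name
  miss <- is.na(idx)
  if (any(miss)) {
    idx[miss] <- match(device_id[miss], registry$model_name)
  }
  out <- tibble::tibble(
    device_id = as.character(device_id),
    model_name = ifelse(is.na(idx), "unknown", registry$model_name[idx]),
    canonical_id = ifelse(is.na(idx), NA_character_,
                          registry$canonical_id[idx]),
    slope = registry$slope[ifelse(is.na(idx), 1L, idx)],
    intercept = registry$intercept[ifelse(is.na(idx), 1L, idx)],
    r_squared = registry$r_squared[ifelse(is.na(idx), 1L, idx)],
    source = ifelse(is.na(idx), NA_character_,
                    registry$source[ifelse(is.na(idx), 1L, idx)])
  )
  out$slope[is.na(idx)] <- NA_real_
  out$intercept[is.na(idx)] <- NA_real_
  out$r_squared[is.na(idx)] <- NA_real_
  dplyr::mutate(out, calibrated = is.finite(slope) & is.finite(intercept))
}

#' Extract one model's calibration from the registry
#'
#' @param model Canonical model name or device ID.
#' @inheritParams resolve_device
#' @return A [device_calibration()].
#' @examples
#' registry_calibration("Galaxy S7")
#' @export
registry_calibration <- function(model, registry = default_registry()) {
  row <- resolve_device(model, registry)
  if (!row$calibrated) {
    stop("no calibration available for '", model, "'", call. = FALSE)
  }
  device_calibration(row$model_name, row$slope, row$intercept,
                     row$r_squared, row$source)
}
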