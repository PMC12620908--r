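#' Read a TAC table with its JSON sidecar
#'
#' TAC tables are tab-separated frame tables: `frame_start` and
#' `frame_duration` columns (minutes), one activity column per named region
#' (kBq/mL) and a required `reference` column. Per-measurement metadata
#' (injected dose in MBq, age in years, group, centre, session, arm and
#' region volumes in mL) lives in a JSON sidecar with the same stem.
#'
#' @param path Path to the `.tsv` table; the sidecar is `<stem>.json`.
#' @return A `tac_table`: list with `frames` ([frame_schedule()]), `tacs`
#'   (frames x regions matrix), `ref` (reference activities) and `meta`
#'   (sidecar list).
#' @export
read_tacs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("frame_start", "frame_duration", "reference")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("TAC table schema violation; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  frames <- frame_schedule(tab$frame_start, tab$frame_duration)
  region_cols <- setdiff(names(tab), need)
  sidecar_path <- paste0(sub("\\.tsv$", "", path), ".json")
  meta <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else {
    stop("missing JSON sidecar: ", sidecar_path, call. = FALSE)
  }
  .validate_sidecar(meta, region_cols)
  out <- list(frames = frames,
              tacs = as.matrix(tab[region_cols]),
              ref = tab$reference,
              meta = meta)
  class(out) <- "tac_table"
  out
}

.SIDE_FIELDS <- c("meas_id", "subject", "group", "centre", "session", "arm",
                  "age", "dose", "region_volumes")

.validate_sidecar <- function(meta, region_cols) {
  missing_fields <- setdiff(.SIDE_FIELDS, names(meta))
  if (length(missing_fields)) {
    stop("sidecar schema violation; missing field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  vols <- meta$region_volumes
  if (length(region_cols) && !all(region_cols %in% names(vols))) {
    stop("sidecar `region_volumes` must name every region column; missing: ",
         paste(setdiff(region_cols, names(vols)), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a TAC table and its JSON sidecar
#'
#' Values are written at 10 significant digits so that
#' `write_tacs(read_tacs(x))` round-trips numerically.
#'
#' @param x A `tac_table` (see [read_tacs()]).
#' @param path Output `.tsv` path; the sidecar is written alongside.
#' @return `path`, invisibly.
#' @export
write_tacs <- function(x, path) {
  stopifnot(inherits(x, "tac_table"))
  tab <- data.frame(frame_start = x$frames$frame_start,
                    frame_duration = x$frames$frame_duration,
                    check.names = FALSE)
  for (r in colnames(x$tacs)) tab[[r]] <- x$tacs[, r]
  tab$reference <- x$ref
  fmt <- function(v) formatC(v, format = "g", digits = 10)
  out <- as.data.frame(lapply(tab, fmt), check.names = FALSE)
  names(out) <- names(tab)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar_path <- paste0(sub("\\.tsv$", "", path), ".json")
  jsonlite::write_json(x$meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Assemble a modelling dataset from TAC tables
#'
#' Binds per-measurement `tac_table`s (plus one fitted reference-curve
#' parameter set per measurement) into the long-format dataset consumed by
#' [build_design()] and [simba_fit()].
#'
#' @param tables List of `tac_table`s.
#' @param ref_params List of [ref_curve_params()] (one per measurement), e.g.
#'   from [fit_reference()]; order matches `tables`.
#' @return A `simba_data` object: list with `meta` (one row per measurement),
#'   `regions` (region, volume), `tacs` (long tibble: meas_id, region, frame
#'   midpoint/duration, activity) and `ref_params` (named by meas_id).
#' @export
simba_data <- function(tables, ref_params) {
  stopifnot(length(tables) == length(ref_params))
  meta <- dplyr::bind_rows(lapply(tables, function(x) {
    m <- x$meta
    tibble::tibble(meas_id = as.character(m$meas_id),
                   subject = as.character(m$subject),
                   group = as.character(m$group),
                   centre = as.character(m$centre),
                   session = as.character(m$session),
                   arm = as.character(m$arm),
                   age = as.numeric(m$age),
                   dose = as.numeric(m$dose))
  }))
  if (anyDuplicated(meta$meas_id)) stop("duplicate meas_id", call. = FALSE)
  vols <- lapply(tables, function(x) unlist(x$meta$region_volumes))
  region_names <- colnames(tables[[1]]$tacs)
  for (v in vols) {
    if (!all(region_names %in% names(v))) {
      stop("region names inconsistent across measurements", call. = FALSE)
    }
  }
  regions <- tibble::tibble(region = region_names,
                            volume = unlist(vols[[1]])[region_names])
  tacs <- dplyr::bind_rows(lapply(tables, function(x) {
    tibble::tibble(
      meas_id = as.character(x$meta$meas_id),
      region = rep(region_names, each = nrow(x$frames)),
      frame_mid = rep(x$frames$frame_mid, length(region_names)),
      frame_duration = rep(x$frames$frame_duration, length(region_names)),
      y = as.vector(x$tacs[, region_names]))
  }))
  names(ref_params) <- meta$meas_id
  ref_curves <- lapply(tables, `[[`, "ref")
  names(ref_curves) <- meta$meas_id
  out <- list(meta = meta, regions = regions, tacs = tacs,
              ref_params = ref_params, ref_curves = ref_curves)
  class(out) <- "simba_data"
  out
}

#' @export
print.simba_data <- function(x, ...) {
  cat(sprintf("<simba_data: %d measurements, %d regions, %d TACs, %d frames total>\n",
              nrow(x$meta), nrow(x$regions),
              nrow(dplyr::distinct(x$tacs, .data$meas_id, .data$region)),
              nrow(x$tacs)))
  invisible(x)
}
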