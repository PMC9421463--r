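#' Default scan-type recognition rules
#'
#' A reconstruction of a typical multi-scanner recognition table: one regular
#' expression per scan type, matched case-insensitively against the series
#' description (and, as a fallback, the protocol name concatenated with the
#' image type). Site-specific deployments should extend or replace this table
#' via [read_scan_type_rules()].
#'
#' @return A tibble with columns `scan_type`, `pattern`, `priority`,
#'   `scanner_scope`.
#' @export
#' @examples
#' default_scan_type_rules()
default_scan_type_rules <- function() {
  tibble::tibble(
    scan_type = c("T1w", "FLAIR", "T2w", "T2starw", "SWI", "bold", "dwi",
                  "asl", "fieldmap-pepolar"),
    pattern = c(
      "mprage|t1w|t1[\\-_ ]?(3d|sag|mpr)|spgr|tfl3d",
      "flair",
      "t2w|t2[\\-_ ]?(tse|spc|space)",
      "t2\\*|t2star|gre[\\-_ ]?field",
      "swi|susceptib",
      "bold|rest|rs[\\-_ ]?f?mri|task|ep2d[\\-_ ]?(bold|pace)",
      "dwi|dti|diff|ep2d[\\-_ ]?diff",
      "asl|pcasl|pasl|perfusion",
      "pepolar|top[\\-_ ]?up|dist[\\-_ ]?corr|fieldmap|_fmap"
    ),
    priority = seq_len(9L),
    scanner_scope = NA_character_
  )
}

#' Read a scan-type rule table from TSV
#'
#' Expects tab-delimited UTF-8 text with a header row and columns `scan_type`,
#' `pattern`, `priority` and optionally `scanner_scope`.
#'
#' @param path Path to the TSV file.
#' @return A validated rules tibble.
#' @export
read_scan_type_rules <- function(path) {
  rules <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_rules(rules)
  rules
}

validate_rules <- function(rules) {
  need <- c("scan_type", "pattern", "priority")
  missing_cols <- setdiff(need, names(rules))
  if (length(missing_cols)) {
    stop("rule table lacks column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(rules) == 0L) stop("rule table is empty", call. = FALSE)
  if (anyDuplicated(rules$priority)) {
    stop("rule priorities must be unique", call. = FALSE)
  }
  for (i in seq_len(nrow(rules))) {
    ok <- tryCatch({ grepl(rules$pattern[i], "x", perl = TRUE); TRUE },
                   error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) {
      stop("invalid regular expression in rule for scan_type '",
           rules$scan_type[i], "': ", rules$pattern[i], call. = FALSE)
    }
  }
  invisible(rules)
}

#' Classify scan types from acquisition metadata
#'
#' Applies a rule table of regular expressions to scan metadata records.
#' Matching is case-insensitive; the series description is tried first and,
#' when no rule matches it, the protocol name concatenated with the image type
#' is tried. Among matching rules the one with the smallest `priority` wins,
#' independent of row order. Records matching no rule are labelled
#' `"unknown"`.
#'
#' @param meta A data frame of scan metadata, one row per scan, with at least a
#'   `series_description` column; `protocol_name` and `image_type` columns are
#'   used for the fallback match when present.
#' @param rules A rule table as returned by [default_scan_type_rules()] or
#'   [read_scan_type_rules()].
#' @return `meta` as a tibble with a `scan_type` column appended (or replaced).
#' @export
#' @examples
#' meta <- tibble::tibble(scan_id = "s1", series_description = "t1_mprage_sag_p2")
#' classify_scan_type(meta, default_scan_type_rules())$scan_type
classify_scan_type <- function(meta, rules = default_scan_type_rules()) {
  validate_rules(rules)
  meta <- tibble::as_tibble(meta)
  if (!"series_description" %in% names(meta)) {
    stop("metadata must contain a 'series_description' column", call. = FALSE)
  }
  rules <- dplyr::arrange(rules, .data$priority)
  desc <- as.character(meta$series_description)
  proto <- if ("protocol_name" %in% names(meta)) as.character(meta$protocol_name) else rep("", nrow(meta))
  itype <- if ("image_type" %in% names(meta)) as.character(meta$image_type) else rep("", nrow(meta))
  proto[is.na(proto)] <- ""; itype[is.na(itype)] <- ""; desc[is.na(desc)] <- ""
  fallback <- trimws(paste(proto, itype))
  classify_one <- function(d, f) {
    for (i in seq_len(nrow(rules))) {
      if (grepl(rules$pattern[i], d, perl = TRUE, ignore.case = TRUE)) return(rules$scan_type[i])
    }
    for (i in seq_len(nrow(rules))) {
      if (nzchar(f) && grepl(rules$pattern[i], f, perl = TRUE, ignore.case = TRUE)) return(rules$scan_type[i])
    }
    "unknown"
  }
  meta$scan_type <- purrr::map2_chr(desc, fallback, classify_one)
  meta
}

#' Session-level metadata consistency checks
#'
#' Verifies, within one MRI session, that the study identifier is concordant
#' across scans, that no two scans share a series UID (duplicates), that each
#' series is complete against its expected file count, and that parameters
#' declared invariant are consistent across scans of the same type.
#'
#' @param scans A data frame with one row per scan of a single session.
#'   Recognised columns: `scan_id`, `session_id`, `study_id`, `series_uid`,
#'   `n_files`, `expected_files`, `scan_type`, plus any acquisition parameter
#'   columns named in `invariant_params`.
#' @param invariant_params Character vector of parameter columns that must not
#'   differ between scans sharing a `scan_type` (default: repetition/echo
#'   time and voxel size if present).
#' @return A tibble of issues with columns `session_id`, `issue_kind`,
#'   `scan_ids` (comma-separated, sorted) and `detail`; zero rows means the
#'   session passes.
#' @export
check_session_consistency <- function(scans,
                                      invariant_params = c("tr", "te", "voxel_size")) {
  scans <- tibble::as_tibble(scans)
  if (nrow(scans) == 0L) stop("empty scan list", call. = FALSE)
  if ("session_id" %in% names(scans) && dplyr::n_distinct(scans$session_id) > 1L) {
    stop("scans must all belong to one session", call. = FALSE)
  }
  ses <- if ("session_id" %in% names(scans)) scans$session_id[1] else NA_character_
  issues <- list()
  add <- function(kind, ids, detail) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      session_id = ses, issue_kind = kind,
      scan_ids = paste(sort(ids), collapse = ","), detail = detail)
  }

  if (nrow(scans) > 1L && "study_id" %in% names(scans)) {
    sid <- unique(scans$study_id[!is.na(scans$study_id)])
    if (length(sid) > 1L) {
      add("studyid_discordant", scans$scan_id,
          paste("study ids:", paste(sort(sid), collapse = " vs ")))
    }
  }

  if (nrow(scans) > 1L && "series_uid" %in% names(scans)) {
    dup <- scans |>
      dplyr::filter(!is.na(.data$series_uid)) |>
      dplyr::group_by(.data$series_uid) |>
      dplyr::filter(dplyr::n() > 1L) |>
      dplyr::ungroup()
    for (uid in unique(dup$series_uid)) {
      ids <- dup$scan_id[dup$series_uid == uid]
      add("duplicate_series", ids, paste("shared series uid", uid))
    }
  }

  if (all(c("n_files", "expected_files") %in% names(scans))) {
    inc <- scans |> dplyr::filter(!is.na(.data$expected_files),
                                  .data$n_files < .data$expected_files)
    for (i in seq_len(nrow(inc))) {
      add("incomplete_series", inc$scan_id[i],
          sprintf("%d of %d files", inc$n_files[i], inc$expected_files[i]))
    }
  } else if ("n_files" %in% names(scans)) {
    message("no 'expected_files' column: completeness check skipped")
  }

  if ("scan_type" %in% names(scans)) {
    for (p in intersect(invariant_params, names(scans))) {
      bad <- scans |>
        dplyr::filter(!is.na(.data[[p]])) |>
        dplyr::group_by(.data$scan_type) |>
        dplyr::filter(dplyr::n() > 1L, dplyr::n_distinct(.data[[p]]) > 1L) |>
        dplyr::ungroup()
      for (st in unique(bad$scan_type)) {
        ids <- bad$scan_id[bad$scan_type == st]
        add("parameter_inconsistent", ids,
            sprintf("parameter '%s' differs across %s scans", p, st))
      }
    }
  }

  if (length(issues) == 0L) {
    return(tibble::tibble(session_id = character(), issue_kind = character(),
                          scan_ids = character(), detail = character()))
  }
  dplyr::bind_rows(issues) |> dplyr::arrange(.data$issue_kind, .data$scan_ids)
}
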